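# Fixed report column schema; numbers at 6 significant digits,
# p-values in scientific notation, for deterministic diff-able output.
.report_cols <- c("chrom", "pair_class", "K", "scheme", "mean_IO",
                  "mean_IA", "mean_IC", "zeta", "zeta_IA", "lambda_zeta",
                  "p_approx", "sig_flag", "reliable", "cv_a", "cv_b",
                  "zs_a", "zs_b")

.fmt_num <- function(x, scientific = FALSE) {
  ifelse(is.na(x), "NA",
         formatC(x, digits = 6, format = if (scientific) "e" else "g"))
}

.format_report <- function(res) {
  d <- res$chromosomes[, .report_cols]
  for (col in c("mean_IO", "mean_IA", "mean_IC", "zeta", "zeta_IA",
                "lambda_zeta", "cv_a", "cv_b", "zs_a", "zs_b"))
    d[[col]] <- .fmt_num(d[[col]])
  d$p_approx <- .fmt_num(res$chromosomes$p_approx, scientific = TRUE)
  d
}

#' Write an analysis report as TSV
#'
#' One row per (chromosome, pair class), in natural chromosome order
#' with the ABA-BAB class first, followed by commented genome-summary
#' lines. Numbers are printed with 6 significant digits (p-values in
#' scientific notation).
#'
#' @param res a `coloc_analysis` from [analyze_colocalization()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(res, path) {
  stopifnot(inherits(res, "coloc_analysis"))
  d <- .format_report(res)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("# trackcoloc report: ", res$track_a, " (A) vs ", res$track_b,
           " (B), mode ", res$mode),
    paste0("# cv_thr=", res$cv_thr, " min_pairs=", res$min_pairs,
           " scheme=", res$scheme_setting),
    vapply(names(res$summary), function(cl) {
      s <- res$summary[[cl]]
      paste0("# summary ", cl, ": tested=", s$n_chromosomes_tested,
             " exceed_005=", s$n_exceeding_005, " exceed_001=",
             s$n_exceeding_001, " binomial_p=", .fmt_num(s$binomial_p, TRUE),
             " class_share=", .fmt_num(s$class_share))
    }, character(1L)),
    paste0("# class_divergence: ks_p=",
           .fmt_num(res$class_divergence$ks_p, TRUE), " mw_p=",
           .fmt_num(res$class_divergence$mw_p, TRUE)),
    paste0("# recommended_class=", res$recommended_class))
  writeLines(hdr, con)
  writeLines(paste(names(d), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(d)), sep = "\t")), con)
  invisible(path)
}

#' Write an analysis report as HTML
#'
#' Contains exactly the numbers of the TSV report (same formatting; no
#' recomputation), as a minimal standalone page.
#'
#' @inheritParams write_report_tsv
#' @return `path`, invisibly.
#' @export
write_report_html <- function(res, path) {
  stopifnot(inherits(res, "coloc_analysis"))
  d <- .format_report(res)
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x))
  row_html <- function(cells, tag = "td")
    paste0("<tr>", paste0("<", tag, ">", esc(cells), "</", tag, ">",
                          collapse = ""), "</tr>")
  smry <- vapply(names(res$summary), function(cl) {
    s <- res$summary[[cl]]
    paste0("<li><b>", cl, "</b>: ", s$n_exceeding_005, "/",
           s$n_chromosomes_tested,
           " chromosomes exceed the Pr=0.05 threshold (binomial p = ",
           .fmt_num(s$binomial_p, TRUE), "), class share ",
           .fmt_num(s$class_share), "</li>")
  }, character(1L))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>trackcoloc report</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font:13px monospace}</style>",
    "</head><body>",
    paste0("<h1>Colocalization report: ", esc(res$track_a), " (A) vs ",
           esc(res$track_b), " (B)</h1>"),
    paste0("<p>Mode: ", res$mode, "; cv_thr = ", res$cv_thr,
           "; min_pairs = ", res$min_pairs, "; scheme = ",
           res$scheme_setting, "</p>"),
    "<h2>Genome summary</h2><ul>", smry,
    paste0("<li>Class divergence: KS p = ",
           .fmt_num(res$class_divergence$ks_p, TRUE),
           ", Mann-Whitney p = ",
           .fmt_num(res$class_divergence$mw_p, TRUE), "</li>"),
    paste0("<li>Recommended class: ", res$recommended_class, "</li>"),
    "</ul>",
    "<h2>Per-chromosome results</h2><table>",
    row_html(names(d), "th"),
    vapply(seq_len(nrow(d)), function(i)
      row_html(unlist(d[i, ], use.names = FALSE)), character(1L)),
    "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Dump a pair table as TSV
#'
#' @param pairs pair table from [track_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
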