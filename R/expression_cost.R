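# Transcription/splicing time-cost model.
#
# The model asks how much longer an intron-bearing gene takes to express
# than an intron-less one: RNA polymerase II transcribes roughly 1-1.5 kbp
# per minute and removing one intron from the pre-mRNA takes on the order
# of 3 minutes. With a mean exonic content of 1 kbp and a mean intron of
# 0.25 kbp, an 8-intron gene is ~3 kbp (2-3 min of transcription plus at
# least 3 min of splicing) while its intron-less derivative is ~1 kbp and
# finished in under a minute. Splicing is largely co-transcriptional, so
# whether per-intron splicing times add is left as an explicit mode.

#' Cost-model parameters
#'
#' @param transcription_rate_range Transcription rate interval in kbp per
#'   minute, default `c(1, 1.5)`.
#' @param splice_time_per_intron Minutes to remove one intron, default 3.
#' @param mean_intron_length Mean intron length in kbp, default 0.25.
#' @param mean_exonic_length Mean total exonic length in kbp, default 1.
#' @return Object of class `cost_params`.
#' @export
cost_params <- function(transcription_rate_range = c(1, 1.5),
                        splice_time_per_intron = 3,
                        mean_intron_length = 0.25,
                        mean_exonic_length = 1) {
  p <- list(transcription_rate_range = as.numeric(transcription_rate_range),
            splice_time_per_intron = as.numeric(splice_time_per_intron),
            mean_intron_length = as.numeric(mean_intron_length),
            mean_exonic_length = as.numeric(mean_exonic_length))
  if (length(p$transcription_rate_range) != 2 ||
      any(p$transcription_rate_range <= 0) ||
      diff(p$transcription_rate_range) < 0)
    stop("transcription_rate_range must be a positive interval [lower, upper]")
  if (p$splice_time_per_intron <= 0 || p$mean_intron_length <= 0 ||
      p$mean_exonic_length <= 0)
    stop("all cost parameters must be strictly positive")
  structure(p, class = "cost_params")
}

#' Total gene length implied by an intron count
#'
#' `mean_exonic_length + n_introns * mean_intron_length`, in kbp.
#'
#' @param n_introns Non-negative intron count (vectorized).
#' @param p A `cost_params`.
#' @return Gene length(s) in kbp.
#' @export
gene_length <- function(n_introns, p = cost_params()) {
  if (any(n_introns < 0)) stop("n_introns must be non-negative")
  p$mean_exonic_length + n_introns * p$mean_intron_length
}

#' Transcription-time interval for a gene of a given length
#'
#' @param length_kbp Gene length in kbp (vectorized, positive).
#' @param p A `cost_params`.
#' @return For scalar input, `c(min, max)` minutes (fast rate gives the
#'   minimum); for vector input a two-column matrix.
#' @export
transcription_time <- function(length_kbp, p = cost_params()) {
  if (any(length_kbp <= 0)) stop("length_kbp must be positive")
  r <- p$transcription_rate_range
  out <- cbind(min = length_kbp / r[2], max = length_kbp / r[1])
  if (length(length_kbp) == 1) {
    c(min = unname(out[1, 1]), max = unname(out[1, 2]))
  } else {
    out
  }
}

#' Total expression time cost of a gene with a given intron count
#'
#' The splicing lower bound depends on the mode: `"serial_minimum"`
#' (default) charges a single per-intron splicing time whenever at least
#' one intron is present, reflecting co-transcriptional splicing where
#' intron removals overlap; `"per_intron"` charges
#' `n_introns * splice_time_per_intron`, the stricter fully-serial model.
#'
#' @param n_introns Non-negative intron count.
#' @param p A `cost_params`.
#' @param mode `"serial_minimum"` or `"per_intron"`.
#' @return Object of class `cost_estimate`: list with `n_introns`,
#'   `gene_length` (kbp), `transcription_time` (`c(min, max)` minutes),
#'   `splicing_time_lower_bound`, `total_time_lower_bound` and
#'   `total_time_upper_bound` (transcription max + splicing bound), minutes.
#' @export
total_cost <- function(n_introns, p = cost_params(),
                       mode = c("serial_minimum", "per_intron")) {
  mode <- match.arg(mode)
  if (n_introns < 0) stop("n_introns must be non-negative")
  len <- gene_length(n_introns, p)
  tt <- transcription_time(len, p)
  splice <- if (n_introns == 0) 0
            else if (mode == "serial_minimum") p$splice_time_per_intron
            else n_introns * p$splice_time_per_intron
  structure(list(n_introns = n_introns,
                 gene_length = len,
                 transcription_time = tt,
                 splicing_time_lower_bound = splice,
                 total_time_lower_bound = unname(tt["min"]) + splice,
                 total_time_upper_bound = unname(tt["max"]) + splice,
                 mode = mode),
            class = "cost_estimate")
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf(paste0("<cost_estimate (%s): %d intron(s), %.3f kbp, ",
                     "transcription %.2f-%.2f min, splicing >= %.2f min, ",
                     "total >= %.2f min>\n"),
              x$mode, x$n_introns, x$gene_length,
              x$transcription_time["min"], x$transcription_time["max"],
              x$splicing_time_lower_bound, x$total_time_lower_bound))
  invisible(x)
}

#' Per-gene cost table for a set of intron counts
#'
#' @param n_introns Named or unnamed vector of intron counts (names become
#'   gene ids).
#' @param p A `cost_params`.
#' @param mode See [total_cost()].
#' @param path Optional TSV output path.
#' @return data.frame with lengths (kbp, 3 decimals) and times (minutes,
#'   2 decimals) per gene.
#' @export
cost_table <- function(n_introns, p = cost_params(),
                       mode = c("serial_minimum", "per_intron"),
                       path = NULL) {
  mode <- match.arg(mode)
  ids <- if (!is.null(names(n_introns))) names(n_introns)
         else paste0("gene", seq_along(n_introns))
  rows <- lapply(seq_along(n_introns), function(i) {
    ce <- total_cost(n_introns[[i]], p, mode)
    data.frame(gene_id = ids[i],
               n_introns = ce$n_introns,
               gene_length_kbp = round(ce$gene_length, 3),
               transcription_min = round(ce$transcription_time[["min"]], 2),
               transcription_max = round(ce$transcription_time[["max"]], 2),
               splicing_lower_bound = round(ce$splicing_time_lower_bound, 2),
               total_lower_bound = round(ce$total_time_lower_bound, 2),
               total_upper_bound = round(ce$total_time_upper_bound, 2),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
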