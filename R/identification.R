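#' Aggregate per-match probabilities into compound hits
#'
#' A *hit* is a candidate compound whose reference spectra matched a
#' query feature. Each individual match carries a P(TP); the hit carries
#' their arithmetic mean (`avg_p1`, with `avg_p0 = 1 - avg_p1`) and a
#' retain/exclude decision at the shortlisting threshold (retained when
#' `avg_p1 >= threshold`; ties retain).
#'
#' @param matches tibble with one row per scored spectral match, columns
#'   `compound` (candidate InChIKey) and `ptp`; an optional `tensor_id`
#'   column (the RPLC/HRMS feature being annotated) is carried through
#'   and grouped on.
#' @param threshold shortlisting threshold on the average P(TP)
#'   (default 0.50).
#' @return A tibble with one row per hit: `compound`, `n_matches`,
#'   `avg_p1`, `avg_p0`, `decision`.
#' @export
aggregate_hits <- function(matches, threshold = 0.5) {
  stopifnot(is.data.frame(matches),
            all(c("compound", "ptp") %in% names(matches)))
  if (nrow(matches) == 0L) {
    stop("Cannot aggregate an empty match list into a hit.", call. = FALSE)
  }
  stopifnot(all(matches$ptp >= 0 & matches$ptp <= 1))
  keys <- intersect(c("tensor_id", "compound"), names(matches))
  out <- dplyr::summarise(
    dplyr::group_by(matches, dplyr::across(dplyr::all_of(keys))),
    n_matches = dplyr::n(),
    avg_p1 = mean(.data$ptp),
    .groups = "drop"
  )
  out$avg_p0 <- 1 - out$avg_p1
  out$decision <- ifelse(out$avg_p1 >= threshold, "retain", "exclude")
  out
}

#' Identification probability from the number of shortlisted hits
#'
#' The identification probability (IP) of one RPLC/HRMS tensor is 1/N
#' over the N retained candidate hits, expressed as a percentage: a
#' single surviving hit yields 100%, five indistinguishable candidates
#' 20%. N = 0 ("not detected") yields `NA`; see [ip_label()].
#'
#' @param n_retained non-negative integer vector of shortlisted hit
#'   counts.
#' @return Numeric vector of IPs in percent (`NA` where `n_retained`
#'   is 0).
#' @export
identification_probability <- function(n_retained) {
  if (any(n_retained < 0)) stop("`n_retained` must be >= 0.", call. = FALSE)
  ifelse(n_retained == 0, NA_real_, 100 / n_retained)
}

#' @rdname identification_probability
#' @param ip numeric IP vector, possibly containing `NA`.
#' @param digits rounding used for display.
#' @return `ip_label()` formats IPs for reporting, rendering `NA` as
#'   `"nd"` (not detected).
#' @export
ip_label <- function(ip, digits = 1) {
  ifelse(is.na(ip), "nd", paste0(round(ip, digits), "%"))
}

#' Top-X identification probability
#'
#' Rank-based alternative to the shortlist IP: the occurrence frequency
#' of true-positive matches among the X top-ranked hits, 100 * N / X.
#'
#' @param n_tp_in_top_x number of true positives among the top X
#'   (0 <= n <= x).
#' @param x size of the top list (>= 1).
#' @return Percentage.
#' @export
top_x_probability <- function(n_tp_in_top_x, x) {
  stopifnot(x >= 1, n_tp_in_top_x >= 0)
  if (any(n_tp_in_top_x > x)) {
    stop("`n_tp_in_top_x` cannot exceed `x`.", call. = FALSE)
  }
  100 * n_tp_in_top_x / x
}

#' Relative improvement between two identification probabilities
#'
#' @param before,after IPs in percent (`before > 0`).
#' @return `100 * (after - before) / before`, the percentage increment.
#' @export
ip_improvement <- function(before, after) {
  if (any(before <= 0)) stop("`before` must be > 0.", call. = FALSE)
  100 * (after - before) / before
}

#' Identify query features from scored matches
#'
#' Full per-tensor identification: matches are aggregated into compound
#' hits, hits are shortlisted at the average-P(TP) threshold, and the
#' identification probability 1/N is computed per tensor.
#'
#' @param matches tibble with columns `tensor_id`, `compound`, `ptp`.
#' @param threshold shortlisting threshold (default 0.50).
#' @return A tibble of class `nta_identification`, one row per tensor:
#'   `tensor_id`, `n_hits`, `n_retained`, `ip`, `ip_label`. The per-hit
#'   table is attached as `attr(, "hits")`.
#' @export
identify_features <- function(matches, threshold = 0.5) {
  stopifnot(all(c("tensor_id", "compound", "ptp") %in% names(matches)))
  hits <- aggregate_hits(matches, threshold = threshold)
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$tensor_id),
    n_hits = dplyr::n(),
    n_retained = sum(.data$decision == "retain"),
    .groups = "drop"
  )
  out$ip <- identification_probability(out$n_retained)
  out$ip_label <- ip_label(out$ip)
  attr(out, "hits") <- hits
  class(out) <- c("nta_identification", class(out))
  out
}

#' Panel-level identification summary
#'
#' Averages per-tensor identification probabilities over a panel (e.g.
#' all spiked compounds in one matrix), the quantity whose before/after
#' comparison measures the benefit of probability-aided annotation.
#'
#' @param identification an [identify_features()] result or any tibble
#'   with an `ip` column.
#' @param na.rm drop not-detected tensors (default `TRUE`).
#' @return A one-row tibble with `mean_ip`, `n_tensor`, `n_detected`.
#' @export
panel_summary <- function(identification, na.rm = TRUE) {
  ip <- identification$ip
  tibble::tibble(mean_ip = mean(ip, na.rm = na.rm),
                 n_tensor = length(ip),
                 n_detected = sum(!is.na(ip)))
}

#' Plot per-tensor identification probabilities
#'
#' @param object an [identify_features()] result.
#' @param ... unused.
#' @return A ggplot bar chart of IP per tensor; not-detected tensors are
#'   shown at zero height and annotated "nd".
#' @exportS3Method ggplot2::autoplot
autoplot.nta_identification <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$ip_plot <- ifelse(is.na(df$ip), 0, df$ip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tensor_id, y = .data$ip_plot)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$ip_label), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "identification probability (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
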