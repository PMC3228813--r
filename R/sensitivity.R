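#' Build an artificial genome of element fragments embedded in null sequence
#'
#' For every element and every requested fragment size `s`, each possible
#' start offset yields one fragment (`len - s + 1` fragments per element).
#' Fragments are interleaved with spacers of non-repetitive null sequence
#' sized so fragments make up `density` of the total genome (10% in the
#' standard benchmark); spacers are consumed without replacement from
#' `null_pool`, starting at a seed-chosen offset, so no spacer sequence is
#' reused (reuse would itself create artifactual high-copy oligos).
#'
#' @param elements Named character vector of full-length element sequences.
#' @param sizes Fragment lengths in bp (e.g. 30, 40, 50 for a young SINE
#'   family; 30–200 for older ones).  Sizes below the annotator's minimum
#'   detectable length are kept but flagged in the truth table.
#' @param null_pool A single long null sequence (e.g. one record of
#'   [simulate_null_genome()]) supplying spacers.
#' @param density Fraction of the artificial genome made of fragments.
#' @param seed Optional seed for the spacer start offset.
#' @param min_detectable Length below which a size is flagged
#'   (`25` for the default annotator geometry).
#' @return A list with `genome` (one named record) and `truth`, a tibble with
#'   `chrom`, `start`, `end`, `element`, `size`, `offset` (1-based within the
#'   element) and `flagged_short`.
#' @export
make_fragment_genome <- function(elements, sizes, null_pool, density = 0.10,
                                 seed = NULL, min_detectable = 25L) {
  if (length(density) != 1L || !is.numeric(density) || density <= 0 || density >= 1)
    stop("`density` must be in (0, 1)", call. = FALSE)
  elements <- as_seq_character(elements, "elements")
  null_pool <- paste(as_seq_character(null_pool, "null_pool"), collapse = "")
  sizes <- sort(unique(as.integer(sizes)))
  if (!is.null(seed)) set.seed(seed)

  frags <- purrr::map(names(elements), function(nm) {
    len <- nchar(elements[[nm]])
    purrr::map(sizes[sizes <= len], function(s) {
      offsets <- seq_len(len - s + 1L)
      tibble(element = nm, size = s, offset = offsets,
             seq = substring(elements[[nm]], offsets, offsets + s - 1L))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(frags) == 0L)
    stop("no fragments: every requested size exceeds every element length",
         call. = FALSE)

  spacer_len <- as.integer(round(frags$size * (1 - density) / density))
  total_spacer <- sum(spacer_len)
  pool_len <- nchar(null_pool)
  if (pool_len < total_spacer)
    stop("null_pool too short: need ", total_spacer, " bp of spacer, have ",
         pool_len, call. = FALSE)
  offset0 <- if (pool_len > total_spacer)
    sample.int(pool_len - total_spacer, 1L) - 1L else 0L
  spacer_end <- offset0 + cumsum(spacer_len)
  spacer_start <- spacer_end - spacer_len + 1L
  spacers <- substring(null_pool, spacer_start, spacer_end)

  pieces <- character(2L * nrow(frags))
  pieces[c(TRUE, FALSE)] <- spacers
  pieces[c(FALSE, TRUE)] <- frags$seq
  genome <- paste(pieces, collapse = "")
  starts <- cumsum(spacer_len + c(0L, head(frags$size, -1L)))
  truth <- tibble(
    chrom = "fragment_genome",
    start = starts,
    end = starts + frags$size,
    element = frags$element,
    size = frags$size,
    offset = frags$offset,
    flagged_short = frags$size < min_detectable
  )
  list(genome = c(fragment_genome = genome), truth = truth)
}

#' Fragment detection sensitivity by size and by position
#'
#' A fragment counts as detected when at least `min_overlap` of its bp
#' overlap any annotated region (1 bp — "any overlap" — unless a stricter
#' fraction is requested for sensitivity analyses).  Detection fractions are
#' summarized per fragment size, and positionally as a trailing running
#' average over 10 consecutive start offsets within the source element —
#' the resolution at which detectability varies along an element.
#'
#' @param truth Truth tibble from [make_fragment_genome()].
#' @param regions Annotated regions of the same artificial genome.
#' @param min_overlap Minimum overlapping bp (default 1), or a fraction of
#'   fragment size if `overlap_frac` is given.
#' @param overlap_frac Optional minimum overlap as a fraction of fragment
#'   size; overrides `min_overlap`.
#' @param run_window Positional running-average window (start offsets).
#' @return A `sensitivity_curve` object: list with `by_size` (size,
#'   n_fragments, detected, sensitivity) and `by_position` (element, size,
#'   offset, running-average sensitivity).
#' @export
measure_sensitivity <- function(truth, regions, min_overlap = 1L,
                                overlap_frac = NULL, run_window = 10L) {
  run_window <- assert_count1(run_window, "run_window")
  need <- if (is.null(overlap_frac)) rep(as.integer(min_overlap), nrow(truth))
          else pmax(1L, as.integer(ceiling(overlap_frac * truth$size)))
  truth$detected <- overlap_bp(truth, regions) >= need
  by_size <- truth |>
    dplyr::group_by(size = .data$size) |>
    dplyr::summarise(n_fragments = dplyr::n(), sensitivity = mean(.data$detected),
                     detected = sum(.data$detected), .groups = "drop") |>
    dplyr::select("size", "n_fragments", "detected", "sensitivity")
  by_position <- truth |>
    dplyr::group_by(.data$element, .data$size) |>
    dplyr::arrange(.data$offset, .by_group = TRUE) |>
    dplyr::mutate(sensitivity = running_mean(as.numeric(.data$detected),
                                             run_window)) |>
    dplyr::ungroup() |>
    dplyr::select("element", "size", "offset", "sensitivity")
  structure(list(by_size = by_size, by_position = by_position,
                 detected = truth$detected),
            class = "sensitivity_curve")
}

# per-interval overlap (bp) with the union of annotated regions, same record set
overlap_bp <- function(truth, regions) {
  out <- integer(nrow(truth))
  if (nrow(regions) == 0L || nrow(truth) == 0L) return(out)
  for (chr in unique(truth$chrom)) {
    ti <- which(truth$chrom == chr)
    ri <- which(regions$chrom == chr)
    if (!length(ri)) next
    q <- IRanges::IRanges(start = truth$start[ti] + 1L, end = truth$end[ti])
    s <- IRanges::reduce(IRanges::IRanges(start = regions$start[ri] + 1L,
                                          end = regions$end[ri]))
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                            s[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[ti[as.integer(names(agg))]] <- as.integer(agg)
  }
  out
}

# trailing running mean, window w; first w-1 entries average what is available
running_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("# Fragment detection sensitivity\n")
  print(x$by_size)
  invisible(x)
}

#' @export
tidy.sensitivity_curve <- function(x, ...) x$by_size

#' @export
glance.sensitivity_curve <- function(x, ...) {
  tibble(n_sizes = nrow(x$by_size),
         n_fragments = sum(x$by_size$n_fragments),
         overall_sensitivity = sum(x$by_size$detected) / sum(x$by_size$n_fragments))
}

#' @export
autoplot.sensitivity_curve <- function(object, which = c("position", "size"), ...) {
  which <- match.arg(which)
  if (which == "size") {
    ggplot2::ggplot(object$by_size,
                    ggplot2::aes(x = .data$size, y = 100 * .data$sensitivity)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "fragment size (bp)", y = "% fragments detected") +
      ggplot2::ylim(0, 100) + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$by_position,
                    ggplot2::aes(x = .data$offset, y = 100 * .data$sensitivity,
                                 colour = factor(.data$size))) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(ggplot2::vars(.data$element)) +
      ggplot2::labs(x = "fragment start position in element",
                    y = "% detected (running average of 10 starts)",
                    colour = "size (bp)") +
      ggplot2::ylim(0, 100) + ggplot2::theme_minimal()
  }
}

#' Interpolate detection sensitivity across fragment sizes
#'
#' Fits a cubic spline through the measured (size, sensitivity) points,
#' clamps predictions to `[0, 1]`, and extrapolates as a constant beyond the
#' measured range.  With exactly two points the spline degenerates to the
#' straight line between them; with fewer, a step function is returned with a
#' warning.
#'
#' @param curve A `sensitivity_curve` or a tibble with `size` and
#'   `sensitivity`.
#' @return A vectorized function mapping fragment length to sensitivity.
#' @export
interpolate_sensitivity <- function(curve) {
  df <- if (inherits(curve, "sensitivity_curve")) curve$by_size else curve
  df <- dplyr::arrange(dplyr::distinct(df, .data$size, .keep_all = TRUE), .data$size)
  if (nrow(df) == 0L) stop("no measured sizes to interpolate", call. = FALSE)
  if (nrow(df) == 1L) {
    warning("only one measured size; returning a constant sensitivity function",
            call. = FALSE)
    s <- df$sensitivity[1L]
    return(function(len) rep(s, length(len)))
  }
  fn <- stats::splinefun(df$size, df$sensitivity, method = "natural")
  lo <- min(df$size); hi <- max(df$size)
  function(len) pmin(1, pmax(0, fn(pmin(pmax(len, lo), hi))))
}

#' Predict how many repetitive bp an annotator missed
#'
#' Divides the observed detected-fragment count at each size by the
#' size-specific detection sensitivity, approximating the true number of
#' fragments present; the predicted minus observed totals, weighted by size,
#' estimate the repetitive bp the annotator failed to report.  Sizes with
#' zero sensitivity cannot be corrected and are excluded with a report
#' rather than silently divided.
#'
#' @param observed Tibble with `size` and `detected` (fragment counts).
#' @param sensitivity_fn A function from [interpolate_sensitivity()].
#' @return A list with `per_size` (size, detected, sensitivity,
#'   predicted_true, missed_bp), `missed_bp`, `predicted_bp` and
#'   `excluded_sizes`.
#' @export
predict_missed_bp <- function(observed, sensitivity_fn) {
  sens <- sensitivity_fn(observed$size)
  excluded <- observed$size[sens <= 0]
  if (length(excluded))
    warning("sensitivity is 0 at size(s) ", paste(excluded, collapse = ", "),
            "; excluded from the correction", call. = FALSE)
  keep <- sens > 0
  per_size <- tibble(
    size = observed$size[keep],
    detected = observed$detected[keep],
    sensitivity = sens[keep],
    predicted_true = observed$detected[keep] / sens[keep]
  ) |>
    dplyr::mutate(missed_bp = (.data$predicted_true - .data$detected) * .data$size)
  list(per_size = per_size,
       missed_bp = sum(per_size$missed_bp),
       predicted_bp = sum(per_size$predicted_true * per_size$size),
       excluded_sizes = excluded)
}
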