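#' Annotate cloud-dense regions of a genome
#'
#' Scans every record for oligo start positions whose oligo (or its reverse
#' complement) is a cloud member, then applies the demarcation criterion: a
#' window of `window` consecutive oligo start positions is *dense* when at
#' least `ceiling(min_frac * window)` of them are members (8 of 10 at the
#' defaults).  The union of all dense windows, taken as maximal runs of oligo
#' positions, is reported as nucleotide intervals `[a, b + k)` — so the
#' shortest possible annotation is `window + k - 1` nt (25 nt at k = 16).
#' Windows never span record boundaries or positions whose oligo contains a
#' non-ACGT symbol: a run of positions interrupted by an assembly gap is
#' scanned piecewise, and pieces shorter than `window` yield nothing.
#'
#' @param genome Sequences to scan (character vector, `DNAStringSet`, or
#'   FASTA path).
#' @param clouds A [build_clouds()] / [build_esp_clouds()] result.
#' @param window Number of consecutive oligo start positions per window.
#' @param min_frac Member fraction required for a window to be dense.
#' @return A tibble of class `pc_regions` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `length` and `posterior` (1 until a
#'   false-positive calibration assigns real values; see
#'   [assign_posteriors()]).  Regions are sorted and non-overlapping within a
#'   record.  Records shorter than `k + window - 1` nt are skipped with a
#'   warning.
#' @examples
#' fam <- strrep("ACGGTTACCAGTGGAAT", 4)
#' clouds <- build_esp_clouds(rep(fam, 5), cloud_params(1, 2, 4, 40, 40), k = 8)
#' annotate_repeats(c(chr = fam), clouds)
#' @export
annotate_repeats <- function(genome, clouds, window = 10L, min_frac = 0.8) {
  stopifnot(inherits(clouds, "cloud_set"))
  window <- assert_count1(window, "window")
  if (length(min_frac) != 1L || !is.numeric(min_frac) || is.na(min_frac) ||
      min_frac <= 0 || min_frac > 1)
    stop("`min_frac` must be in (0, 1]", call. = FALSE)
  genome <- as_seq_character(genome, "genome")
  k <- attr(clouds, "k")
  need <- ceiling(min_frac * window)
  codes <- member_codes(clouds)
  min_len <- k + window - 1L

  too_short <- nchar(genome) < min_len
  if (any(too_short)) {
    warning("skipping ", sum(too_short), " record(s) shorter than ", min_len,
            " nt: ", paste(head(names(genome)[too_short], 5L), collapse = ", "),
            call. = FALSE)
    genome <- genome[!too_short]
  }

  res <- purrr::map2(genome, names(genome), function(seq, chrom) {
    m <- cpp_member_scan(seq, k, codes)
    runs_to_regions(m, chrom, k, window, need)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L)
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), posterior = double())
  new_pc_regions(out, k = k, window = window, min_frac = min_frac)
}

# m: per-oligo-position member indicator (1/0/NA); returns region tibble
runs_to_regions <- function(m, chrom, k, window, need) {
  npos <- length(m)
  if (npos < window) return(NULL)
  ann <- logical(npos)
  valid <- !is.na(m)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= window)) {
    a <- starts[i]; b <- ends[i]
    x <- m[a:b]
    # rolling member sum over trailing windows of length `window`
    roll <- as.numeric(stats::filter(x, rep(1, window), sides = 1))
    dense_end <- which(roll[window:length(x)] >= need) + window - 1L
    if (!length(dense_end)) next
    # mark all positions covered by a dense window via a difference array
    d <- integer(length(x) + 1L)
    ws <- dense_end - window + 1L
    for (j in seq_along(ws)) {
      d[ws[j]] <- d[ws[j]] + 1L
      d[dense_end[j] + 1L] <- d[dense_end[j] + 1L] - 1L
    }
    ann[a:b] <- cumsum(d[-length(d)]) > 0L
  }
  if (!any(ann)) return(NULL)
  ra <- rle(ann)
  re <- cumsum(ra$lengths)
  rs <- re - ra$lengths + 1L
  keep <- ra$values
  tibble(
    chrom = chrom,
    start = rs[keep] - 1L,
    end = re[keep] - 1L + k,
    length = re[keep] - rs[keep] + k,
    posterior = 1.0
  )
}

new_pc_regions <- function(df, k = NA_integer_, window = NA_integer_,
                           min_frac = NA_real_) {
  structure(df, k = as.integer(k), window = as.integer(window),
            min_frac = min_frac,
            class = c("pc_regions", class(tibble())))
}

#' Merge nearby annotated regions
#'
#' Regions on the same record separated by at most `gap` bp are merged.  The
#' merged region's posterior is recomputed from its new length when an
#' [estimate_fp_table()] result is supplied, otherwise it is the maximum of
#' the inputs.
#'
#' @param regions A `pc_regions` tibble (sorted per record).
#' @param gap Maximum separation in bp to bridge (0 merges touching regions).
#' @param fp_table Optional `fp_table` for posterior recomputation.
#' @return A merged `pc_regions` tibble.
#' @export
merge_regions <- function(regions, gap = 0L, fp_table = NULL) {
  gap <- assert_count1(gap, "gap", min = 0)
  if (nrow(regions) == 0L) return(regions)
  merged <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      new_block = .data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                           default = -Inf) + gap,
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      posterior = max(.data$posterior), .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start) |>
    dplyr::select("chrom", "start", "end", "length", "posterior") |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(fp_table))
    merged$posterior <- 1 - fp_lookup(fp_table, merged$length)
  new_pc_regions(merged, k = attr(regions, "k"),
                 window = attr(regions, "window"),
                 min_frac = attr(regions, "min_frac"))
}

#' Read and write BED6 interval files
#'
#' Annotated regions are written as BED6: chrom, start, end (0-based
#' half-open), a region id, a score of `round(1000 * posterior)` (half-up, so
#' scores are stable across platforms), and strand `"."`.  `read_bed()`
#' accepts 3- to 6-column BED and returns a tibble.
#'
#' @param regions A `pc_regions` tibble (or any tibble with chrom/start/end
#'   and optionally posterior).
#' @param path File path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` a tibble with
#'   columns `chrom`, `start`, `end`, `name`, `score`, `strand` (missing
#'   columns filled with defaults) plus `length` and `posterior`
#'   (`score/1000`).
#' @export
write_bed <- function(regions, path) {
  posterior <- if ("posterior" %in% names(regions)) regions$posterior else 1
  score <- floor(1000 * posterior + 0.5)  # round half up, bit-exact
  df <- tibble(
    chrom = regions$chrom,
    start = as.integer(regions$start),
    end = as.integer(regions$end),
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = as.integer(score),
    strand = if ("strand" %in% names(regions)) regions$strand else "."
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_
  df$score <- if (ncol(df) >= 5L) as.numeric(df[[5L]]) else NA_real_
  df$strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else "."
  df |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     length = .data$end - .data$start,
                     .data$name, .data$score, .data$strand,
                     posterior = .data$score / 1000)
}

#' Mask intervals of a genome with N
#'
#' Replaces the given 0-based half-open intervals with `N`, which removes
#' them from any subsequent oligo scan (windows containing `N` are skipped).
#' Used by element-specific runs to restrict scanning to the complement of an
#' existing annotation.
#'
#' @param genome Named character vector / `DNAStringSet` / FASTA path.
#' @param bed A tibble with `chrom`, `start`, `end` (e.g. from [read_bed()]).
#' @return A named character vector of the same lengths.
#' @export
mask_regions <- function(genome, bed) {
  genome <- as_seq_character(genome, "genome")
  for (i in seq_len(nrow(bed))) {
    chrom <- bed$chrom[i]
    if (!chrom %in% names(genome)) next
    s <- bed$start[i]; e <- bed$end[i]
    e <- min(e, nchar(genome[[chrom]]))
    if (s >= e) next
    substr(genome[[chrom]], s + 1L, e) <- strrep("N", e - s)
  }
  genome
}
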