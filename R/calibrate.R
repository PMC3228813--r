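#' Simulate a dinucleotide-preserving non-repetitive null genome
#'
#' Emits, for every `window_bp` window of every record, a first-order Markov
#' chain whose transition probabilities equal the window's observed
#' dinucleotide conditional frequencies (initial state drawn from the
#' window's mononucleotide frequencies).  Local base composition and
#' dinucleotide structure are preserved; repeats — which are higher-order
#' structure — are destroyed.  Non-ACGT runs are copied through verbatim at
#' the same coordinates and the chain restarts after each one, so output
#' records have exactly the input lengths.
#'
#' @param source Sequences whose composition is matched (character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param window_bp Window size for frequency matching; 1 Mbp tracks local
#'   isochore-scale composition in mammalian genomes.
#' @param seed Optional integer seed (set once before simulation; a fixed
#'   seed gives byte-identical output).
#' @return A named character vector of simulated records.
#' @export
simulate_null_genome <- function(source, window_bp = 1e6, seed = NULL) {
  if (length(window_bp) != 1L || !is.numeric(window_bp) || window_bp < 2)
    stop("`window_bp` must be a single number >= 2", call. = FALSE)
  window_bp <- as.integer(window_bp)
  source <- as_seq_character(source, "source")
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::imap_chr(source, function(seq, nm) {
    n <- nchar(seq)
    starts <- seq.int(1L, n, by = window_bp)
    pieces <- purrr::map_chr(starts, function(s) {
      e <- min(s + window_bp - 1L, n)
      win <- substr(seq, s, e)
      cnt <- cpp_dinuc_counts(win)
      if (sum(cnt$mono) < 2) {
        warning("window ", s - 1L, "-", e, " of record '", nm,
                "' has fewer than 2 ACGT nt; copied verbatim", call. = FALSE)
        return(win)
      }
      cpp_simulate_markov(win, cnt$trans, cnt$mono)
    })
    paste(pieces, collapse = "")
  })
  setNames(out, names(source))
}

#' Length-dependent false-positive probabilities from a null annotation
#'
#' Annotating a simulated non-repetitive genome with the same clouds and
#' parameters as the real genome yields pure false positives.  For every
#' region length `L` observed in the real annotation, the false-positive
#' probability is estimated as the (scan-size-normalized) ratio of simulated
#' to real region counts at that exact length, clamped to `[0, 1]`:
#' `FP(L) = min(1, n_sim(L) * (real_bp / sim_bp) / n_real(L))`.
#'
#' Lookups for lengths absent from the table fall back to the nearest
#' *smaller* listed length, and below the smallest listed length to the
#' overall mean FP rate (total normalized simulated count over total real
#' count).  Setting `monotone = TRUE` replaces the raw rates with their
#' isotonic non-increasing-in-length fit, a smoothing for sparse length
#' tails; the raw estimate is the default.
#'
#' @param real_regions,sim_regions Annotations of the real and the simulated
#'   genome, produced with identical parameters.
#' @param real_bp,sim_bp Scanned bp in each genome; equal-length simulation
#'   (the standard workflow) gives a ratio of 1, which is the default when
#'   both are `NULL`.
#' @param monotone Apply isotonic (non-increasing in length) smoothing.
#' @return A tibble of class `fp_table` with columns `length`, `n_real`,
#'   `n_sim`, `fp`, and attributes `normalization` (real_bp/sim_bp) and
#'   `mean_fp`.
#' @export
estimate_fp_table <- function(real_regions, sim_regions, real_bp = NULL,
                              sim_bp = NULL, monotone = FALSE) {
  ratio <- if (is.null(real_bp) || is.null(sim_bp)) 1 else real_bp / sim_bp
  if (!is.finite(ratio) || ratio <= 0)
    stop("`real_bp`/`sim_bp` must give a positive finite ratio", call. = FALSE)
  n_real <- dplyr::count(real_regions, length = .data$length, name = "n_real")
  n_sim <- dplyr::count(sim_regions, length = .data$length, name = "n_sim")
  tab <- dplyr::full_join(n_real, n_sim, by = "length") |>
    tidyr::replace_na(list(n_real = 0L, n_sim = 0L)) |>
    dplyr::arrange(.data$length)
  total_real <- sum(tab$n_real)
  mean_fp <- if (total_real > 0) min(1, sum(tab$n_sim) * ratio / total_real) else 0
  tab <- tab |>
    dplyr::filter(.data$n_real > 0L) |>
    dplyr::mutate(fp = pmin(1, .data$n_sim * ratio / .data$n_real))
  if (monotone && nrow(tab) > 1L) {
    iso <- stats::isoreg(tab$length, -tab$fp)  # non-increasing in length
    tab$fp <- pmin(1, pmax(0, -iso$yf))
  }
  structure(tab, normalization = ratio, mean_fp = mean_fp,
            class = c("fp_table", class(tibble())))
}

#' @export
print.fp_table <- function(x, ...) {
  cat(sprintf("# FP table: %d lengths, mean FP rate %.4f, normalization %.3f\n",
              nrow(x), attr(x, "mean_fp"), attr(x, "normalization")))
  NextMethod()
}

#' @export
tidy.fp_table <- function(x, ...) as_tibble(x)

#' @export
glance.fp_table <- function(x, ...) {
  tibble(n_lengths = nrow(x), mean_fp = attr(x, "mean_fp"),
         normalization = attr(x, "normalization"))
}

#' Total false-positive lookup for arbitrary region lengths
#'
#' @param fp_table An [estimate_fp_table()] result.
#' @param lengths Integer vector of region lengths.
#' @return FP probabilities in `[0, 1]` (nearest-smaller-length fallback,
#'   then the overall mean rate).
#' @export
fp_lookup <- function(fp_table, lengths) {
  stopifnot(inherits(fp_table, "fp_table"))
  if (nrow(fp_table) == 0L)
    return(rep(attr(fp_table, "mean_fp"), length(lengths)))
  idx <- findInterval(lengths, fp_table$length)
  out <- rep(attr(fp_table, "mean_fp"), length(lengths))
  hit <- idx >= 1L
  out[hit] <- fp_table$fp[idx[hit]]
  pmin(1, pmax(0, out))
}

#' Assign length-based posterior probabilities of repetitiveness
#'
#' Each region's posterior is one minus its length's false-positive
#' probability; coordinates and order are untouched.
#'
#' @param regions A `pc_regions` tibble.
#' @param fp_table An [estimate_fp_table()] result.
#' @return `regions` with `posterior` set.
#' @export
assign_posteriors <- function(regions, fp_table) {
  regions$posterior <- 1 - fp_lookup(fp_table, regions$length)
  regions
}

#' Expected truly repetitive basepairs
#'
#' The posterior-weighted annotated total, `sum(length * posterior)`: the
#' number of annotated bp expected to be genuinely repetitive once expected
#' false positives are subtracted.
#'
#' @param regions Regions with posteriors assigned.
#' @return A single number (bp).
#' @export
expected_true_bp <- function(regions) {
  sum(regions$length * regions$posterior)
}

#' Serialize a false-positive table
#'
#' Tab-separated columns (length, n_real, n_sim, fp) under a header recording
#' the normalization ratio and mean rate.
#'
#' @param fp_table An `fp_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fp_table <- function(fp_table, path) {
  stopifnot(inherits(fp_table, "fp_table"))
  header <- sprintf("# pclouds fp_table\tnormalization=%.10g\tmean_fp=%.10g",
                    attr(fp_table, "normalization"), attr(fp_table, "mean_fp"))
  writeLines(header, path)
  readr::write_tsv(as_tibble(fp_table), path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fp_table
#' @export
read_fp_table <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- strsplit(strsplit(sub("^#\\s*", "", header), "\t")[[1]][-1], "=")
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2L)), vapply(kv, `[`, "", 1L))
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("length", "n_real", "n_sim", "fp"),
                        col_types = "iiid", progress = FALSE)
  structure(as_tibble(df), normalization = vals[["normalization"]],
            mean_fp = vals[["mean_fp"]],
            class = c("fp_table", class(tibble())))
}

#' @export
autoplot.fp_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$fp)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "annotated region length (bp)",
                  y = "false-positive probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
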