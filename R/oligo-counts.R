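#' Count fixed-length oligonucleotides in a sequence set
#'
#' Slides a window of `k` nucleotides along every record and counts each
#' distinct oligo (forward strand, as written).  Counting is case-insensitive,
#' never crosses record boundaries, and any window containing a non-ACGT
#' symbol (assembly gaps, IUPAC ambiguity codes) is skipped entirely and does
#' not contribute to `total_positions`.
#'
#' @param seqs A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file (gzip allowed).
#' @param k Oligo word length in nucleotides (16 is the usual choice for
#'   mammalian-sized genomes; see [recommended_oligo_length()]).
#' @param prune_below Drop oligos with count strictly below this value after
#'   counting (a memory measure for large scans; the default keeps
#'   everything).  Pruned totals are retained in `total_positions`.
#'
#' @return A tibble of class `oligo_counts` with columns `oligo` and `count`,
#'   sorted by decreasing count then oligo, and attributes `k`,
#'   `total_positions` and `prune_below`.
#' @examples
#' count_oligos(c(chr1 = "ACGTACGTAC"), k = 4)
#' @seealso [build_clouds()], [write_oligo_counts()]
#' @export
count_oligos <- function(seqs, k, prune_below = 1L) {
  k <- assert_count1(k, "k")
  if (k > 26L) stop("`k` larger than 26 is not supported", call. = FALSE)
  prune_below <- assert_count1(prune_below, "prune_below")
  seqs <- as_seq_character(seqs)
  raw <- cpp_count_kmers(seqs, k)
  keep <- raw$count >= prune_below
  oligo <- cpp_decode_oligos(raw$code[keep], k)
  count <- raw$count[keep]
  ord <- order(-count, oligo)
  new_oligo_counts(
    tibble(oligo = oligo[ord], count = count[ord]),
    k = k, total_positions = raw$total_positions, prune_below = prune_below
  )
}

new_oligo_counts <- function(df, k, total_positions, prune_below = 1L) {
  structure(
    df,
    k = as.integer(k),
    total_positions = total_positions,
    prune_below = as.integer(prune_below),
    class = c("oligo_counts", class(tibble()))
  )
}

#' @export
print.oligo_counts <- function(x, ...) {
  cat(sprintf("# Oligo counts: k = %d, %s distinct oligos, %s positions scanned\n",
              attr(x, "k"), format(nrow(x), big.mark = ","),
              format(attr(x, "total_positions"), big.mark = ",")))
  NextMethod()
}

#' @export
glance.oligo_counts <- function(x, ...) {
  tibble(
    k = attr(x, "k"),
    total_positions = attr(x, "total_positions"),
    n_distinct = nrow(x),
    max_count = if (nrow(x)) max(x$count) else 0L
  )
}

#' Smallest oligo length expected to occur less than once by chance
#'
#' For a genome of `N` countable positions and equal nucleotide frequencies, a
#' random oligo of length `l` is expected `N / 4^l` times.  This returns the
#' smallest `l` for which that expectation drops below one — 16 for
#' mammalian-sized genomes (around 2.85 Gbp).
#'
#' @param N Genome (or genome segment) size in bp; must be >= 1.
#' @return An integer word length.
#' @examples
#' recommended_oligo_length(2.85e9)  # 16
#' @export
recommended_oligo_length <- function(N) {
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N < 1)
    stop("`N` must be a single number >= 1", call. = FALSE)
  l <- 1L
  while (N / 4^l >= 1) l <- l + 1L
  l
}

#' Enumerate the Hamming neighborhood of an oligo
#'
#' All oligos of the same length at Hamming distance exactly `d` (substitutions
#' only, ACGT alphabet).  There are `choose(k, d) * 3^d` of them.
#'
#' @param oligo A single ACGT string.
#' @param d Hamming distance, 0 to 3.
#' @return A character vector of oligos (the input itself when `d = 0`).
#' @examples
#' hamming_neighbors("ACGT", 1)
#' @export
hamming_neighbors <- function(oligo, d) {
  if (length(oligo) != 1L || !is.character(oligo) || grepl("[^ACGTacgt]", oligo))
    stop("`oligo` must be a single ACGT string", call. = FALSE)
  if (length(d) != 1L || !is.numeric(d) || is.na(d) || d < 0 || d > 3 || d != floor(d))
    stop("`d` must be 0, 1, 2 or 3", call. = FALSE)
  oligo <- toupper(oligo)
  if (d == 0) return(oligo)
  k <- nchar(oligo)
  if (d > k) return(character(0))
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(oligo, "")[[1]]
  pos_sets <- utils::combn(k, d, simplify = FALSE)
  out <- purrr::map(pos_sets, function(pos) {
    # all 3^d ways to substitute the chosen positions
    alts <- purrr::map(pos, ~ setdiff(bases, chars[.x]))
    grid <- do.call(expand.grid, c(alts, stringsAsFactors = FALSE))
    apply(grid, 1L, function(repl) {
      x <- chars
      x[pos] <- repl
      paste(x, collapse = "")
    })
  })
  unlist(out, use.names = FALSE)
}

#' Expected oligo copy-number spectrum under a Poisson null
#'
#' If `N` oligo positions are drawn uniformly over the `4^k` possible words,
#' the number of distinct oligos appearing exactly `c` times is approximately
#' `4^k * dpois(c, N / 4^k)`.  Comparing this expectation with the observed
#' spectrum shows how far a genome departs from random sequence.
#'
#' @param N Number of scanned oligo start positions (>= 0).
#' @param k Word length.
#' @param cmax Largest copy number to tabulate.
#' @return A tibble with columns `copies` (0..cmax) and `expected`.
#' @seealso [plot_oligo_spectrum()]
#' @export
poisson_oligo_expectation <- function(N, k, cmax) {
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N < 0)
    stop("`N` must be a single number >= 0", call. = FALSE)
  k <- assert_count1(k, "k")
  cmax <- assert_count1(cmax, "cmax", min = 0)
  lambda <- N / 4^k
  tibble(copies = 0:cmax, expected = 4^k * dpois(0:cmax, lambda))
}

#' Observed copy-number spectrum vs the Poisson expectation
#'
#' @param counts An [count_oligos()] table.
#' @param cmax Largest copy number displayed.
#' @return A ggplot comparing the observed number of distinct oligos per copy
#'   number with the Poisson expectation for the same scan.
#' @export
plot_oligo_spectrum <- function(counts, cmax = 20L) {
  stopifnot(inherits(counts, "oligo_counts"))
  cmax <- assert_count1(cmax, "cmax")
  k <- attr(counts, "k")
  obs <- counts |>
    dplyr::count(.data$count, name = "n_oligos") |>
    dplyr::filter(.data$count <= cmax) |>
    dplyr::rename(copies = "count")
  zero <- 4^k - nrow(counts)
  obs <- dplyr::bind_rows(tibble(copies = 0L, n_oligos = zero), obs)
  exp <- poisson_oligo_expectation(attr(counts, "total_positions"), k, cmax)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$copies)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_oligos, shape = "observed")) +
    ggplot2::geom_line(data = exp,
                       ggplot2::aes(y = .data$expected, linetype = "Poisson expectation")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "copy number", y = "distinct oligos",
                  shape = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize an oligo count table
#'
#' Two tab-separated columns (oligo, count) under a `#`-prefixed header line
#' that records `k` and `total_positions`, so the table round-trips.
#'
#' @param counts An `oligo_counts` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_oligo_counts <- function(counts, path) {
  stopifnot(inherits(counts, "oligo_counts"))
  header <- sprintf("# pclouds oligo_counts\tk=%d\ttotal_positions=%.0f\tprune_below=%d",
                    attr(counts, "k"), attr(counts, "total_positions"),
                    attr(counts, "prune_below"))
  writeLines(header, path)
  readr::write_tsv(tibble(oligo = counts$oligo, count = counts$count), path,
                   append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_oligo_counts
#' @export
read_oligo_counts <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  kv <- strsplit(fields[-1], "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- readr::read_tsv(path, comment = "#", col_names = c("oligo", "count"),
                        col_types = "ci", progress = FALSE)
  new_oligo_counts(as_tibble(df),
                   k = as.integer(vals[["k"]]),
                   total_positions = as.numeric(vals[["total_positions"]]),
                   prune_below = as.integer(vals[["prune_below"]]))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
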