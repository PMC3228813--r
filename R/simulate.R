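#' Describe a repeat family to plant in a synthetic genome
#'
#' A family is a random master element plus `copies` descendants, each
#' mutated i.i.d. per site at the stated expected divergence (substitutions
#' drawn uniformly over the three alternatives; an optional
#' transition/transversion bias is available).  Fragmentation truncates
#' copies to emulate decayed elements.
#'
#' @param master_length Master element length in bp.
#' @param copies Number of planted copies.
#' @param divergence Expected per-site substitution fraction from the master,
#'   in `[0, 0.75)`; 0.05 emulates a young family, 0.25 an ancient one.
#' @param fragmentation `"full"` (every copy full length) or a two-element
#'   numeric vector `c(min, max)` giving a uniform range of truncated copy
#'   lengths (a random contiguous piece of the master).
#' @param name Family identifier used in truth tables.
#' @param master Optional explicit master sequence (overrides
#'   `master_length`).
#' @param ts_tv Transition/transversion rate ratio; 1 is the unbiased
#'   default.
#' @return A `repeat_family` spec list.
#' @export
repeat_family <- function(master_length = 300L, copies = 500L,
                          divergence = 0.10, fragmentation = "full",
                          name = "fam1", master = NULL, ts_tv = 1) {
  if (divergence < 0 || divergence >= 0.75)
    stop("`divergence` must be in [0, 0.75)", call. = FALSE)
  if (!is.null(master)) master_length <- nchar(master)
  structure(list(master_length = as.integer(master_length),
                 copies = as.integer(copies), divergence = divergence,
                 fragmentation = fragmentation, name = name, master = master,
                 ts_tv = ts_tv),
            class = "repeat_family")
}

BASES <- c("A", "C", "G", "T")

# mutate a sequence i.i.d. per site; returns list(seq, realized divergence)
mutate_copy <- function(master_chars, divergence, ts_tv = 1) {
  n <- length(master_chars)
  hit <- which(stats::runif(n) < divergence)
  out <- master_chars
  if (length(hit)) {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in hit) {
      alts <- setdiff(BASES, out[i])
      w <- ifelse(alts == transition[[out[i]]], ts_tv, 1)
      out[i] <- sample(alts, 1L, prob = w)
    }
  }
  list(seq = out, divergence = length(hit) / n)
}

#' Generate a genome with planted repeat families and truth annotations
#'
#' Background sequence is drawn from a first-order Markov model (uniform
#' transitions by default), family copies are mutated from their masters and
#' inserted at uniformly random non-overlapping positions, each on a random
#' strand, and a truth table records where every copy went.  Fixed seeds give
#' identical output, so fixtures are reproducible without storing them.
#'
#' @param background_bp Background (non-repeat) length; the genome is
#'   `background_bp` plus all planted copy lengths.
#' @param families A [repeat_family()] or list of them.
#' @param seed Optional integer seed.
#' @param trans Optional 4x4 background transition matrix (rows = from
#'   A,C,G,T), defaults to uniform.
#' @param chrom Record name of the generated genome.
#' @return A list with `genome` (named character vector, one record),
#'   `truth` (tibble: `chrom`, `start`, `end`, `family`, `copy`, `strand`,
#'   `divergence`), and `families` (named list of character vectors: the
#'   planted copy sequences, forward-strand as inserted into their master
#'   orientation, for ESP cloud building).
#' @export
plant_genome <- function(background_bp, families, seed = NULL, trans = NULL,
                         chrom = "chr1") {
  if (inherits(families, "repeat_family")) families <- list(families)
  stopifnot(all(purrr::map_lgl(families, inherits, "repeat_family")))
  background_bp <- assert_count1(background_bp, "background_bp")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trans)) trans <- matrix(0.25, 4, 4)

  background <- cpp_simulate_markov(strrep("A", background_bp), trans,
                                    rep(0.25, 4))

  copies <- purrr::map(families, function(fam) {
    master <- fam$master %||% paste(sample(BASES, fam$master_length, replace = TRUE),
                                    collapse = "")
    mchars <- strsplit(master, "")[[1]]
    purrr::map(seq_len(fam$copies), function(i) {
      mut <- mutate_copy(mchars, fam$divergence, fam$ts_tv)
      s <- mut$seq
      if (!identical(fam$fragmentation, "full")) {
        len <- sample(fam$fragmentation[1]:fam$fragmentation[2], 1L)
        len <- min(len, length(s))
        from <- sample.int(length(s) - len + 1L, 1L)
        s <- s[from:(from + len - 1L)]
      }
      fwd <- paste(s, collapse = "")
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      list(family = fam$name, copy = i, fwd = fwd,
           planted = if (strand == "+") fwd else reverse_complement(fwd),
           strand = strand, divergence = mut$divergence, master = master)
    })
  }) |> purrr::flatten()

  total_planted <- sum(purrr::map_int(copies, ~ nchar(.x$planted)))
  if (background_bp <= total_planted)
    stop("background_bp (", background_bp, ") must exceed total planted bp (",
         total_planted, ")", call. = FALSE)

  if (length(copies) == 0L) {
    return(list(genome = setNames(background, chrom),
                truth = tibble(chrom = character(), start = integer(),
                               end = integer(), family = character(),
                               copy = integer(), strand = character(),
                               divergence = double()),
                families = list(), masters = character()))
  }

  # uniform non-overlapping placement: cut the background at sorted random
  # points and insert one copy at each cut
  n <- length(copies)
  ord <- sample.int(n)
  cuts <- sort(sample.int(background_bp - 1L, n))
  bg_pieces <- substring(background, c(1L, cuts + 1L), c(cuts, background_bp))
  planted_seqs <- purrr::map_chr(copies[ord], "planted")
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- bg_pieces
  pieces[seq(2L, 2L * n, by = 2L)] <- planted_seqs
  genome <- paste(pieces, collapse = "")

  lens <- nchar(planted_seqs)
  starts <- cuts + c(0L, cumsum(head(lens, -1L)))
  truth <- tibble(
    chrom = chrom,
    start = starts,
    end = starts + lens,
    family = purrr::map_chr(copies[ord], "family"),
    copy = purrr::map_int(copies[ord], "copy"),
    strand = purrr::map_chr(copies[ord], "strand"),
    divergence = purrr::map_dbl(copies[ord], "divergence")
  ) |> dplyr::arrange(.data$start)

  fam_seqs <- split(purrr::map_chr(copies, "fwd"),
                    purrr::map_chr(copies, "family"))
  fam_seqs <- purrr::imap(fam_seqs, function(x, nm)
    setNames(x, paste0(nm, "_copy", seq_along(x))))
  masters <- purrr::map_chr(copies, "master")
  masters <- masters[!duplicated(purrr::map_chr(copies, "family"))]
  names(masters) <- unique(purrr::map_chr(copies, "family"))

  list(genome = setNames(genome, chrom), truth = truth,
       families = fam_seqs, masters = masters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write truth intervals as BED6
#'
#' @param truth A [plant_genome()] truth table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  df <- tibble(
    chrom = truth$chrom,
    start = as.integer(truth$start),
    end = as.integer(truth$end),
    name = paste0(truth$family, ":", truth$copy),
    score = 0L,
    strand = truth$strand
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
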