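# Independent oracles and fixture helpers.  These deliberately avoid the
# package's compiled code paths: distances come from character-matrix
# comparison, counting from substring tables, so agreement is meaningful.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive sliding-window oligo counter (ACGT-only windows)
naive_count <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  words <- substring(seq, 1:(n - k + 1), k:n)
  words <- words[!grepl("[^ACGT]", words)]
  table(words)
}

# brute-force Hamming neighborhood by filtering the full 4^k word list
enumerate_neighbors <- function(oligo, d) {
  k <- nchar(oligo)
  all_words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                           stringsAsFactors = FALSE))
  ref <- strsplit(oligo, "")[[1]]
  dist <- vapply(strsplit(all_words, ""),
                 function(w) sum(w != ref), integer(1))
  all_words[dist == d]
}

# exhaustive cloud constructor: descending-count seed processing with
# lexicographic tie-break, seed-count radius, breadth-first chains of
# distance-1 steps; plain R on a Hamming distance matrix
oracle_clouds <- function(oligo, count, params, k) {
  n <- length(oligo)
  chars <- do.call(rbind, strsplit(oligo, ""))
  D <- matrix(0L, n, n)
  for (i in seq_len(n))
    D[i, ] <- as.integer(rowSums(chars != matrix(chars[i, ], n, k, byrow = TRUE)))
  adj1 <- D == 1L
  ord <- order(-count, oligo)
  cores <- ord[count[ord] >= params$core]
  cloud <- integer(n)
  is_seed <- logical(n)
  next_id <- 0L
  for (s in cores) {
    if (cloud[s] != 0L) next
    next_id <- next_id + 1L
    cloud[s] <- next_id
    is_seed[s] <- TRUE
    c0 <- count[s]
    radius <- if (c0 >= params$ext3) 3L else if (c0 >= params$ext2) 2L else
      if (c0 >= params$ext1) 1L else 0L
    frontier <- s
    depth <- 0L
    while (depth < radius && length(frontier)) {
      depth <- depth + 1L
      reach <- which(cloud == 0L & count >= params$lower &
                       Reduce(`|`, lapply(frontier, function(f) adj1[f, ])))
      cloud[reach] <- next_id
      frontier <- reach
    }
  }
  tibble::tibble(oligo = oligo, count = count, cloud = cloud,
                 is_seed = is_seed)[cloud > 0L, ]
}

# random sparse count table over the 4^k oligo universe
random_count_table <- function(k, n_oligos, seed, max_count = 3000L) {
  set.seed(seed)
  universe <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                          stringsAsFactors = FALSE))
  oligo <- sample(universe, n_oligos)
  count <- as.integer(pmax(1, stats::rgeom(n_oligos, prob = 0.02)))
  count[sample(n_oligos, max(1L, n_oligos %/% 20L))] <-
    sample(200:max_count, max(1L, n_oligos %/% 20L), replace = TRUE)
  ord <- order(-count, oligo)
  tibble::tibble(oligo = oligo[ord], count = count[ord])
}

as_oligo_counts <- function(df, k) {
  pclouds:::new_oligo_counts(df, k = k, total_positions = sum(df$count))
}

# a cloud set whose members are exactly the given oligos (no expansion)
literal_cloud_set <- function(oligos, k) {
  build_esp_clouds(setNames(oligos, paste0("o", seq_along(oligos))),
                   cloud_params(1, 1, 1, 1, 1), k = k)
}

# per-base chi-square goodness of fit of simulated transition counts against
# the source's conditional dinucleotide frequencies
dinuc_gof_p <- function(source_seq, sim_seq) {
  src <- pclouds:::cpp_dinuc_counts(source_seq)$trans
  out <- pclouds:::cpp_dinuc_counts(sim_seq)$trans
  p_src <- src / rowSums(src)
  E <- rowSums(out) * p_src
  keep <- E > 5
  stat <- sum((out[keep] - E[keep])^2 / E[keep])
  stats::pchisq(stat, df = sum(keep) - 4, lower.tail = FALSE)
}

planted_bp_recovered <- function(truth, regions) {
  sum(pclouds:::overlap_bp(truth, regions))
}
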