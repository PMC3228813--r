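#' Cutoff parameters for cloud construction
#'
#' Five counts control how oligo clouds form: an oligo needs `core` copies to
#' seed a cloud and `lower` copies to join one, and the seed's own count
#' against the three extension cutoffs decides how far (Hamming distance 1, 2
#' or 3) the cloud may recruit.  The conservative whole-genome setting used
#' for mammalian analyses is (2, 10, 20, 200, 2000); element-specific runs
#' use family-tuned values such as (1, 2, 4, 40, 40) for ancient, diverged
#' families.
#'
#' @param lower Minimum count for cloud membership.
#' @param core Minimum count to seed a cloud.
#' @param ext1,ext2,ext3 Seed-count thresholds enabling expansion to Hamming
#'   distance 1, 2 and 3.
#' @return A `cloud_params` object.
#' @examples
#' cloud_params()                     # the conservative whole-genome setting
#' cloud_params(1, 2, 4, 40, 40)      # a diverged-family setting
#' @export
cloud_params <- function(lower = 2L, core = 10L, ext1 = 20L, ext2 = 200L,
                         ext3 = 2000L) {
  p <- c(lower = lower, core = core, ext1 = ext1, ext2 = ext2, ext3 = ext3)
  if (any(!is.finite(p)) || any(p != floor(p)))
    stop("cloud parameters must be integers", call. = FALSE)
  if (!(1 <= p["lower"] && p["lower"] <= p["core"] && p["core"] <= p["ext1"] &&
        p["ext1"] <= p["ext2"] && p["ext2"] <= p["ext3"]))
    stop("cloud parameters must satisfy 1 <= lower <= core <= ext1 <= ext2 <= ext3",
         call. = FALSE)
  structure(as.list(as.integer(p)) |> setNames(names(p)), class = "cloud_params")
}

#' @export
print.cloud_params <- function(x, ...) {
  cat(sprintf("cloud_params(lower = %d, core = %d, ext = %d/%d/%d)\n",
              x$lower, x$core, x$ext1, x$ext2, x$ext3))
  invisible(x)
}

#' Build oligo clouds from a count table
#'
#' Clusters high-copy oligos into clouds.  Oligos whose count reaches
#' `params$core` are processed in non-increasing count order (ties broken
#' lexicographically); each still-unassigned one seeds a cloud whose radius —
#' 0, 1, 2 or 3 substitutions — is set by comparing the seed's count against
#' the extension cutoffs.  The cloud then grows breadth-first: at each step
#' any unassigned oligo with count at or above `params$lower` that is one
#' substitution away from an admitted member joins, up to `radius` steps from
#' the seed.  An oligo belongs to at most one cloud (first, i.e.
#' highest-count, seed wins).
#'
#' @param counts An [count_oligos()] table.
#' @param params A [cloud_params()] object.
#' @return A tibble of class `cloud_set` with one row per member oligo:
#'   columns `oligo`, `count`, `cloud` (1-based id in seed order), `is_seed`;
#'   attributes `k`, `params` and a `clouds` summary tibble (`cloud`, `seed`,
#'   `radius`, `n_members`).
#' @examples
#' counts <- count_oligos(c(x = strrep("ACGTG", 12)), k = 5)
#' build_clouds(counts, cloud_params(1, 2, 4, 40, 40))
#' @export
build_clouds <- function(counts, params = cloud_params()) {
  stopifnot(inherits(counts, "oligo_counts"), inherits(params, "cloud_params"))
  k <- attr(counts, "k")
  if (nrow(counts) == 0L) {
    return(new_cloud_set(tibble(oligo = character(), count = integer(),
                                cloud = integer(), is_seed = logical()),
                         k = k, params = params,
                         clouds = tibble(cloud = integer(), seed = character(),
                                         radius = integer(), n_members = integer())))
  }
  codes <- cpp_encode_oligos(counts$oligo)
  res <- cpp_build_clouds(codes, counts$count, k,
                          params$lower, params$core,
                          params$ext1, params$ext2, params$ext3)
  keep <- res$cloud > 0L
  members <- tibble(
    oligo = counts$oligo[keep],
    count = counts$count[keep],
    cloud = res$cloud[keep],
    is_seed = res$is_seed[keep]
  ) |>
    dplyr::arrange(.data$cloud, dplyr::desc(.data$is_seed), .data$oligo)
  summary <- tibble(
    cloud = seq_along(res$radius),
    seed = cpp_decode_oligos(res$seed_code, k),
    radius = res$radius
  ) |>
    dplyr::left_join(dplyr::count(members, .data$cloud, name = "n_members"),
                     by = "cloud")
  new_cloud_set(members, k = k, params = params, clouds = summary)
}

new_cloud_set <- function(members, k, params, clouds) {
  structure(
    members,
    k = as.integer(k),
    params = params,
    clouds = clouds,
    class = c("cloud_set", class(tibble()))
  )
}

#' @export
print.cloud_set <- function(x, ...) {
  cat(sprintf("# Cloud set: k = %d, %d clouds, %d member oligos\n",
              attr(x, "k"), nrow(attr(x, "clouds")), nrow(x)))
  NextMethod()
}

#' @export
tidy.cloud_set <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.cloud_set <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    k = attr(x, "k"),
    n_clouds = nrow(attr(x, "clouds")),
    n_members = nrow(x),
    lower = p$lower, core = p$core,
    ext1 = p$ext1, ext2 = p$ext2, ext3 = p$ext3
  )
}

#' Build element-specific clouds from a repeat-family library
#'
#' Counts oligos over all copies of one repeat family (optionally excluding
#' held-out records, e.g. a cross-validation test set) and builds clouds from
#' those counts.  Family-derived clouds pick up fragments of the family in a
#' genome even where whole-genome counts are too diluted to do so.
#'
#' @param family_seqs Sequences of known family copies (character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param params A [cloud_params()] object; diverged families warrant laxer
#'   cutoffs than the whole-genome default.
#' @param k Word length.
#' @param exclude Record names (or indices) to hold out before counting.
#' @return A `cloud_set`, as [build_clouds()].
#' @export
build_esp_clouds <- function(family_seqs, params, k, exclude = NULL) {
  seqs <- as_seq_character(family_seqs, "family_seqs")
  if (!is.null(exclude)) {
    seqs <- if (is.numeric(exclude)) seqs[-exclude] else seqs[setdiff(names(seqs), exclude)]
  }
  if (length(seqs) == 0L)
    stop("all family records were excluded; nothing to build clouds from",
         call. = FALSE)
  build_clouds(count_oligos(seqs, k), params)
}

#' Strand-symmetric cloud membership lookup
#'
#' An oligo is a member if it, or its reverse complement, belongs to any
#' cloud — counting is forward-strand but annotation is strand-agnostic.
#'
#' @param clouds A `cloud_set`.
#' @param oligos Character vector of oligos of the set's word length.
#' @return A logical vector.
#' @export
is_cloud_member <- function(clouds, oligos) {
  stopifnot(inherits(clouds, "cloud_set"))
  k <- attr(clouds, "k")
  if (any(nchar(oligos) != k))
    stop("oligos must have length k = ", k, call. = FALSE)
  oligos <- toupper(oligos)
  oligos %in% clouds$oligo | reverse_complement(oligos) %in% clouds$oligo
}

# member codes (both strands) for the fast position scan
member_codes <- function(clouds) {
  k <- attr(clouds, "k")
  fwd <- cpp_encode_oligos(clouds$oligo)
  unique(c(fwd, cpp_revcomp_codes(fwd, k)))
}

#' Serialize a cloud set
#'
#' Tab-separated columns (oligo, cloud_id, is_seed), sorted, under a header
#' line recording `k` and the five cutoffs; byte-identical for identical
#' inputs, so diff-based regression checks work.
#'
#' @param clouds A `cloud_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clouds <- function(clouds, path) {
  stopifnot(inherits(clouds, "cloud_set"))
  p <- attr(clouds, "params")
  header <- sprintf("# pclouds cloud_set\tk=%d\tlower=%d\tcore=%d\text1=%d\text2=%d\text3=%d",
                    attr(clouds, "k"), p$lower, p$core, p$ext1, p$ext2, p$ext3)
  writeLines(header, path)
  df <- as_tibble(clouds)[, c("oligo", "cloud", "is_seed")] |>
    dplyr::arrange(.data$cloud, .data$oligo) |>
    dplyr::mutate(is_seed = as.integer(.data$is_seed))
  readr::write_tsv(df, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_clouds
#' @export
read_clouds <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- strsplit(strsplit(sub("^#\\s*", "", header), "\t")[[1]][-1], "=")
  vals <- setNames(as.integer(vapply(kv, `[`, "", 2L)), vapply(kv, `[`, "", 1L))
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("oligo", "cloud", "is_seed"),
                        col_types = "cii", progress = FALSE) |>
    dplyr::mutate(is_seed = as.logical(.data$is_seed), count = NA_integer_) |>
    dplyr::select("oligo", "count", "cloud", "is_seed")
  params <- cloud_params(vals[["lower"]], vals[["core"]], vals[["ext1"]],
                         vals[["ext2"]], vals[["ext3"]])
  seeds <- df[df$is_seed, ]
  summary <- tibble(cloud = seeds$cloud, seed = seeds$oligo,
                    radius = NA_integer_) |>
    dplyr::left_join(dplyr::count(df, .data$cloud, name = "n_members"),
                     by = "cloud")
  new_cloud_set(as_tibble(df), k = vals[["k"]], params = params, clouds = summary)
}
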