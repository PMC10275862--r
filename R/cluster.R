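#' Pairwise cluster graph of point mutations
#'
#' Two mutations on the same chromosome are linked when their genomic
#' distance is strictly below `threshold` (1 kb by default). The edge list
#' is computed with a two-pointer sweep over sorted positions, so it is
#' linear in positions plus edges.
#'
#' @param positions Integer vector of 1-based positions on one chromosome of
#'   one clone.
#' @param threshold Distance threshold in bp (strict `<`).
#' @return Tibble with columns `pos_i`, `pos_j` (`pos_i < pos_j`) and
#'   `distance`.
#' @export
build_cluster_graph <- function(positions, threshold = 1000) {
  p <- sort(as.numeric(positions))
  n <- length(p)
  if (n < 2) {
    return(tibble(pos_i = numeric(0), pos_j = numeric(0), distance = numeric(0)))
  }
  is <- js <- vector("list", n)
  lo <- 1L
  for (j in 2:n) {
    while (p[j] - p[lo] >= threshold) lo <- lo + 1L
    if (lo < j) {
      is[[j]] <- p[lo:(j - 1L)]
      js[[j]] <- rep(p[j], j - lo)
    }
  }
  pi <- unlist(is)
  pj <- unlist(js)
  if (is.null(pi)) {
    return(tibble(pos_i = numeric(0), pos_j = numeric(0), distance = numeric(0)))
  }
  tibble(pos_i = pi, pos_j = pj, distance = pj - pi)
}

# component ids for sorted positions: on a line, connected components under
# |p_i - p_j| < t are exactly maximal runs with consecutive gaps < t
sweep_components <- function(sorted_pos, threshold) {
  n <- length(sorted_pos)
  if (n == 0) return(integer(0))
  cumsum(c(1L, as.integer(diff(sorted_pos) >= threshold)))
}

#' Detect clustered point mutations and partition them into components
#'
#' Builds the per-clone, per-chromosome cluster graph (pairs of mutations at
#' distance `< threshold`) and returns its connected components of size at
#' least two. Components larger than `large_threshold` members are
#' kataegis-like mutation showers; the rest are omikli-like clusters.
#'
#' @param mutations Data frame of point mutations with columns `clone_id`,
#'   `chrom`, `pos` (duplicated positions within a clone/chromosome are
#'   counted once).
#' @param threshold Clustering distance in bp (strict `<`).
#' @param large_threshold Component size above which (strict `>`) a
#'   component is kataegis-like.
#' @return Object of class `radmut_clusters`: a list with `components`
#'   (tibble: `clone_id`, `chrom`, `component_id`, `size`, `class`,
#'   `positions` list-column), `members` (tibble: one row per clustered
#'   mutation) and the thresholds used.
#' @export
find_clusters <- function(mutations, threshold = 1000, large_threshold = 5) {
  mutations <- as_tibble(mutations)
  stopifnot(all(c("clone_id", "chrom", "pos") %in% names(mutations)))
  groups <- mutations |>
    distinct(.data$clone_id, .data$chrom, .data$pos) |>
    arrange(.data$clone_id, .data$chrom, .data$pos) |>
    group_by(.data$clone_id, .data$chrom)

  members <- groups |>
    mutate(component_id = sweep_components(.data$pos, .env$threshold)) |>
    group_by(.data$clone_id, .data$chrom, .data$component_id) |>
    filter(n() >= 2) |>
    ungroup()

  components <- members |>
    group_by(.data$clone_id, .data$chrom, .data$component_id) |>
    summarise(size = n(), positions = list(.data$pos), .groups = "drop") |>
    mutate(class = ifelse(.data$size > large_threshold,
                          "kataegis_like", "omikli_like"))

  structure(
    list(components = components, members = members,
         threshold = threshold, large_threshold = large_threshold,
         n_input = nrow(distinct(mutations, .data$clone_id, .data$chrom,
                                 .data$pos))),
    class = "radmut_clusters"
  )
}

#' @export
print.radmut_clusters <- function(x, ...) {
  cat("Clustered point mutations (<", x$threshold, "bp pairwise rule)\n")
  cat("  input mutations: ", x$n_input, "\n")
  cat("  clustered mutations: ", nrow(x$members), " in ",
      nrow(x$components), " components\n", sep = "")
  tab <- table(x$components$class)
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  invisible(x)
}

#' Tally omikli-like and kataegis-like components
#'
#' @param clusters A `radmut_clusters` object.
#' @param by Optional grouping columns of the component table (e.g.
#'   `"clone_id"`).
#' @return Tibble with counts of components and clustered mutations per
#'   class.
#' @export
count_cluster_classes <- function(clusters, by = NULL) {
  comp <- clusters$components
  comp |>
    group_by(across(all_of(c(by, "class")))) |>
    summarise(n_components = n(), n_mutations = sum(.data$size),
              .groups = "drop")
}

#' Inter-mutation distances within clusters
#'
#' One distance per unordered pair of clustered mutations lying within the
#' clustering threshold (i.e. per edge of the cluster graph); each pair is
#' counted once. Distances between mutations of the same component that are
#' farther apart than the threshold (chained clusters) are not counted.
#'
#' @param clusters A `radmut_clusters` object.
#' @param mode `"edges"` (default; pairs under the threshold) or
#'   `"consecutive"` (successive sorted positions within a component).
#' @return Tibble with `clone_id`, `chrom`, `component_id`, `distance` and
#'   `log10_distance`.
#' @export
intermutation_distances <- function(clusters, mode = c("edges", "consecutive")) {
  mode <- match.arg(mode)
  comp <- clusters$components
  if (nrow(comp) == 0) {
    return(tibble(clone_id = character(0), chrom = character(0),
                  component_id = integer(0), distance = numeric(0),
                  log10_distance = numeric(0)))
  }
  rows <- pmap(comp[c("clone_id", "chrom", "component_id", "positions")],
    function(clone_id, chrom, component_id, positions) {
      d <- if (mode == "edges") {
        build_cluster_graph(positions, clusters$threshold)$distance
      } else {
        diff(sort(positions))
      }
      tibble(clone_id = clone_id, chrom = chrom,
             component_id = component_id, distance = d)
    })
  list_rbind(rows) |>
    mutate(log10_distance = log10(.data$distance))
}

#' Six-class spectrum of clustered mutations
#'
#' Restricts classified SNVs to cluster members and tallies the six
#' substitution types, for comparison against the genome-wide spectrum.
#'
#' @param clusters A `radmut_clusters` object.
#' @param classified_snvs Data frame with `clone_id`, `chrom`, `pos` and a
#'   `sbs6` column (see [classify_snv_96()] or [classify_snv_6()]).
#' @param by Grouping columns for the tally (default pooled over clones).
#' @return Tibble with one row per group and substitution type, zero-filled.
#' @export
clustered_spectrum <- function(clusters, classified_snvs, by = NULL) {
  classified_snvs <- as_tibble(classified_snvs)
  members <- clusters$members |>
    select("clone_id", "chrom", "pos")
  clustered <- inner_join(classified_snvs, members,
                          by = c("clone_id", "chrom", "pos"))
  grid <- if (is.null(by)) {
    tibble(sbs6 = sbs6_types())
  } else {
    tidyr::expand_grid(
      distinct(classified_snvs, across(all_of(by))),
      sbs6 = sbs6_types()
    )
  }
  tally <- clustered |>
    group_by(across(all_of(c(by, "sbs6")))) |>
    summarise(n = n(), .groups = "drop")
  left_join(grid, tally, by = c(by, "sbs6")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}
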