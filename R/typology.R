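#' Farm-by-year monthly GRASS probability profiles
#'
#' Averages per-record GRASS probabilities by farm, year and month and
#' assembles one 12-dimensional profile per farm-year. Farm-years with
#' fewer than 12 distinct test months (incomplete annual coverage) are
#' excluded; the exclusion count is attached as an attribute and
#' reported via `message()`.
#'
#' @param records data.frame with `farm_id`, `year`, `month` columns.
#' @param probability numeric GRASS probability per row (or the name of a
#'   column of `records`).
#' @return data.frame with `farm_id`, `year` and columns `m1`..`m12`
#'   (monthly mean probabilities); attribute `n_excluded` counts the
#'   dropped farm-years.
#' @export
build_profiles <- function(records, probability = "probability") {
  if (is.character(probability) && length(probability) == 1L) {
    if (!probability %in% names(records)) {
      stop("column `", probability, "` not found in records", call. = FALSE)
    }
    probability <- records[[probability]]
  }
  if (length(probability) != nrow(records)) {
    stop("`probability` must have one value per record", call. = FALSE)
  }
  fy <- interaction(records$farm_id, records$year, drop = TRUE)
  groups <- split(seq_len(nrow(records)), fy)
  out <- vector("list", length(groups))
  n_excluded <- 0L
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    months <- records$month[idx]
    if (length(unique(months)) < 12L) {
      n_excluded <- n_excluded + 1L
      next
    }
    pm <- tapply(probability[idx], factor(months, levels = 1:12), mean)
    row <- data.frame(farm_id = records$farm_id[idx[1]],
                      year = records$year[idx[1]],
                      stringsAsFactors = FALSE)
    row[paste0("m", 1:12)] <- as.list(as.numeric(pm))
    out[[i]] <- row
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    stop("no farm-year has full 12-month coverage", call. = FALSE)
  }
  out <- out[order(out$farm_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  if (n_excluded > 0L) {
    message(n_excluded, " farm-year(s) excluded for incomplete monthly coverage")
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

# 12-column numeric matrix of a profile table.
profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[paste0("m", 1:12)])
  rownames(m) <- paste(profiles$farm_id, profiles$year, sep = ":")
  m
}

#' Ward.D2 hierarchical clustering of probability profiles
#'
#' Agglomerative clustering of the 12-dimensional farm-year profiles
#' under the Ward.D2 criterion: Euclidean input distances, with the
#' squared-distance Ward update applied through the Lance-Williams
#' recursion (the `"ward.D2"` convention, where the caller does not
#' pre-square distances). Merge heights are monotone nondecreasing.
#'
#' @param profiles profile table from [build_profiles()].
#' @return object of class `grass_typology_tree`: list with the `hclust`
#'   tree and the `profiles` used.
#' @export
ward_d2_cluster <- function(profiles) {
  if (nrow(profiles) < 2L) {
    stop("need at least 2 profiles to cluster", call. = FALSE)
  }
  m <- profile_matrix(profiles)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  structure(list(hclust = hc, profiles = profiles),
            class = "grass_typology_tree")
}

#' @export
print.grass_typology_tree <- function(x, ...) {
  cat(sprintf("Ward.D2 tree over %d farm-year profiles\n",
              nrow(x$profiles)))
  cat(sprintf("  merge heights: %.3g .. %.3g\n",
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut the tree into K clusters and summarize them
#'
#' Cuts the Ward.D2 tree into `K` clusters and computes, per cluster, the
#' mean monthly GRASS-probability curve and the descriptive trait summary
#' used to interpret feeding intensity: milk yield (kg/day), fat and
#' protein (g/100 g), and SFA, MUFA and LCFA expressed in g/100 g of milk
#' fat. Trait summaries average unweighted over all records of the
#' farm-years assigned to the cluster.
#'
#' @param tree `grass_typology_tree` from [ward_d2_cluster()].
#' @param K number of clusters, between 1 and the number of profiles.
#' @param records optional trait records (as from [generate_dataset()])
#'   used for the trait summaries; if `NULL` only curves are produced.
#' @return object of class `grass_cluster_solution`: list with `K`,
#'   `assignments` (farm_id, year, cluster), `cluster_sizes`,
#'   `monthly_curves` (K x 12 matrix), `trait_summary` (data.frame or
#'   `NULL`), and the `tree`.
#' @export
cut_and_summarize <- function(tree, K, records = NULL) {
  stopifnot(inherits(tree, "grass_typology_tree"))
  n <- nrow(tree$profiles)
  K <- check_count(K, "K")
  if (K > n) {
    stop(sprintf("K = %d exceeds the number of profiles (%d)", K, n),
         call. = FALSE)
  }
  cl <- if (K == n) seq_len(n) else stats::cutree(tree$hclust, k = K)
  assignments <- data.frame(farm_id = tree$profiles$farm_id,
                            year = tree$profiles$year,
                            cluster = as.integer(cl),
                            stringsAsFactors = FALSE)
  m <- profile_matrix(tree$profiles)
  curves <- t(vapply(seq_len(K),
                     function(kk) colMeans(m[cl == kk, , drop = FALSE]),
                     numeric(12)))
  dimnames(curves) <- list(paste0("cluster", seq_len(K)), paste0("m", 1:12))
  trait_summary <- NULL
  if (!is.null(records)) {
    need <- c("farm_id", "year", "milk_yield", "fat_pct", "protein_pct",
              "sfa", "mufa", "lcfa")
    missing <- setdiff(need, names(records))
    if (length(missing)) {
      stop("records are missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    rec_cl <- assignments$cluster[match(
      paste(records$farm_id, records$year),
      paste(assignments$farm_id, assignments$year))]
    keep <- !is.na(rec_cl)
    rec <- records[keep, , drop = FALSE]
    rec_cl <- rec_cl[keep]
    per_fat <- function(v) 100 * v / rec$fat_pct  # g/dL milk -> g/100 g fat
    trait_summary <- data.frame(
      cluster = seq_len(K),
      n_records = as.integer(tabulate(rec_cl, nbins = K)),
      milk_yield = tapply_mean(rec$milk_yield, rec_cl, K),
      fat = tapply_mean(rec$fat_pct, rec_cl, K),
      protein = tapply_mean(rec$protein_pct, rec_cl, K),
      sfa_fat = tapply_mean(per_fat(rec$sfa), rec_cl, K),
      mufa_fat = tapply_mean(per_fat(rec$mufa), rec_cl, K),
      lcfa_fat = tapply_mean(per_fat(rec$lcfa), rec_cl, K))
  }
  structure(
    list(K = K, assignments = assignments,
         cluster_sizes = as.integer(tabulate(cl, nbins = K)),
         monthly_curves = curves, trait_summary = trait_summary,
         tree = tree),
    class = "grass_cluster_solution")
}

tapply_mean <- function(v, g, K) {
  out <- rep(NA_real_, K)
  m <- tapply(v, factor(g, levels = seq_len(K)), mean)
  out[as.integer(names(m))] <- as.numeric(m)
  out
}

#' @export
print.grass_cluster_solution <- function(x, ...) {
  cat(sprintf("Ward.D2 cluster solution: K = %d, sizes %s\n",
              x$K, paste(x$cluster_sizes, collapse = "/")))
  invisible(x)
}

#' Flag skimmed-milk clusters
#'
#' Clusters whose mean fat content falls below `fat_threshold` correspond
#' to farms submitting skimmed bulk samples; their spectra describe a
#' modified milk matrix, so their predictions are uninterpretable for
#' feeding and the clusters are flagged for exclusion.
#'
#' @param solution `grass_cluster_solution` with trait summaries.
#' @param fat_threshold fat cutoff in g/100 g (default 1).
#' @return integer vector of flagged cluster ids (possibly empty).
#' @export
flag_skimmed <- function(solution, fat_threshold = 1) {
  stopifnot(inherits(solution, "grass_cluster_solution"))
  if (is.null(solution$trait_summary)) {
    stop("solution has no trait summaries; rerun cut_and_summarize() ",
         "with records", call. = FALSE)
  }
  ts <- solution$trait_summary
  as.integer(ts$cluster[!is.na(ts$fat) & ts$fat < fat_threshold])
}

#' Map clusters to feeding-intensity groups by probability level
#'
#' Orders the (non-excluded) clusters by their overall mean GRASS
#' probability and labels the lowest `n_intensive` as "intensive", the
#' highest `n_extensive` as "extensive", and the rest as "intermediate".
#' A convenience default for simulated cohorts; with real data the
#' mapping is normally read off the cluster curves by eye.
#'
#' @param solution `grass_cluster_solution`.
#' @param exclude cluster ids to leave unmapped (e.g. skimmed clusters
#'   from [flag_skimmed()]).
#' @param n_intensive,n_extensive number of clusters per extreme group.
#' @return named character vector: cluster id -> group.
#' @export
assign_cluster_groups <- function(solution, exclude = integer(0),
                                  n_intensive = 1, n_extensive = 1) {
  stopifnot(inherits(solution, "grass_cluster_solution"))
  ids <- setdiff(seq_len(solution$K), exclude)
  if (length(ids) < n_intensive + n_extensive) {
    stop("not enough unexcluded clusters for the requested group sizes",
         call. = FALSE)
  }
  level <- rowMeans(solution$monthly_curves)[ids]
  ord <- ids[order(level)]
  grp <- rep("intermediate", length(ids))
  names(grp) <- as.character(ord)
  grp[seq_len(n_intensive)] <- "intensive"
  grp[seq(length(ids) - n_extensive + 1, length(ids))] <- "extensive"
  grp[order(as.integer(names(grp)))]
}

#' Per-farm feeding-intensity index
#'
#' Scores each farm-year -1 if its cluster belongs to the "intensive"
#' group and +1 otherwise (the "extensive" and "intermediate" groups both
#' score +1), then sums the scores per farm over years. Farms in the
#' intensive group every observed year are "always-intensive"; farms in
#' the extensive group every year are "always-extensive"; all other farms
#' are "intermediate".
#'
#' @param assignments data.frame with `farm_id`, `year`, `cluster` (as in
#'   a `grass_cluster_solution`), or the solution itself.
#' @param group_map named character vector mapping every cluster id
#'   appearing in `assignments` to one of `"intensive"`, `"extensive"`,
#'   `"intermediate"` (see [assign_cluster_groups()]).
#' @param exclude cluster ids to drop (e.g. flagged skimmed clusters);
#'   farm-years in excluded clusters are removed before scoring.
#' @return data.frame with `farm_id`, `n_years`, `score_sum` (in
#'   \[-n_years, n_years\]), `category`.
#' @export
intensity_index <- function(assignments, group_map, exclude = integer(0)) {
  if (inherits(assignments, "grass_cluster_solution")) {
    assignments <- assignments$assignments
  }
  a <- assignments[!assignments$cluster %in% exclude, , drop = FALSE]
  if (nrow(a) == 0L) stop("no assignments left after exclusion", call. = FALSE)
  unmapped <- setdiff(unique(a$cluster), as.integer(names(group_map)))
  if (length(unmapped)) {
    stop("group_map leaves cluster(s) unmapped: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(group_map),
                 c("intensive", "extensive", "intermediate"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grp <- group_map[as.character(a$cluster)]
  val <- ifelse(grp == "intensive", -1L, 1L)
  out <- do.call(rbind, lapply(split(seq_len(nrow(a)), a$farm_id),
    function(idx) {
      g <- grp[idx]
      data.frame(farm_id = a$farm_id[idx[1]],
                 n_years = length(idx),
                 score_sum = sum(val[idx]),
                 category = if (all(g == "intensive")) "always-intensive"
                            else if (all(g == "extensive")) "always-extensive"
                            else "intermediate",
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$farm_id), , drop = FALSE]
}
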