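#' @title Cluster labeling
#' @name clusters
#' @description
#' Connected-component decomposition of supra-threshold statistic maps.
#' The cluster-forming threshold is stated as an uncorrected per-voxel
#' p-value (0.005 by default throughout the package) and converted to a
#' statistic cutoff through the appropriate reference distribution;
#' voxels strictly above the cutoff form clusters under 6-, 18- or
#' 26-neighbour connectivity (18 by default).
NULL

#' Neighbour offsets for a connectivity scheme
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all).
#' @return integer matrix of (di, dj, dk) offsets.
#' @export
connectivity_offsets <- function(connectivity = 18) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  g[ord > 0 & ord <= lim, , drop = FALSE]
}

# Label connected components among `supra_lin` (1-based linear indices) on a
# grid of the given shape. Returns a list of integer vectors of member
# linear indices, one per component (flood fill / BFS).
.label_components <- function(supra_lin, shape, connectivity = 18) {
  if (!length(supra_lin)) return(list())
  nv <- prod(shape)
  n1 <- shape[1]; n12 <- shape[1] * shape[2]
  lab <- integer(nv)
  lab[supra_lin] <- -1L
  offs <- connectivity_offsets(connectivity)
  noff <- nrow(offs)
  comps <- list()
  cur <- 0L
  for (s in supra_lin) {
    if (lab[s] != -1L) next
    cur <- cur + 1L
    members <- integer(0)
    queue <- s
    lab[s] <- cur
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      members <- c(members, v)
      v0 <- v - 1L
      i <- v0 %% n1
      j <- (v0 %/% n1) %% shape[2]
      k <- v0 %/% n12
      ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- k + offs[, 3]
      ok <- ni >= 0 & ni < shape[1] & nj >= 0 & nj < shape[2] & nk >= 0 & nk < shape[3]
      nb <- 1L + ni[ok] + nj[ok] * n1 + nk[ok] * n12
      nb <- nb[lab[nb] == -1L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    comps[[cur]] <- members
  }
  comps
}

.forming_cutoff <- function(kind, df, forming_threshold_p) {
  if (kind == "t") stats::qt(forming_threshold_p, df, lower.tail = FALSE)
  else if (kind == "F") stats::qf(forming_threshold_p, df[1], df[2], lower.tail = FALSE)
  else stop("stat map kind must be 't' or 'F'")
}

.cluster_table_from_comps <- function(comps, vals, grid, cutoff, connectivity,
                                      df, kind) {
  if (!length(comps)) {
    tab <- data.frame(cluster_id = integer(0), size = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0), peak_z_score = numeric(0))
  } else {
    rows <- lapply(seq_along(comps), function(ci) {
      lin <- comps[[ci]]
      v <- vals[lin]
      pk <- lin[which.max(v)]
      pk0 <- pk - 1L
      idx <- cbind(pk0 %% grid$shape[1],
                   (pk0 %/% grid$shape[1]) %% grid$shape[2],
                   pk0 %/% (grid$shape[1] * grid$shape[2])) + 1L
      xyz <- voxel_centers(grid, idx)
      pz <- if (kind == "t") z_from_t(max(v), df) else z_from_f(max(v), df[1], df[2])
      data.frame(cluster_id = ci, size = length(lin),
                 peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
                 peak_stat = max(v), peak_z_score = pz)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$size), , drop = FALSE]
    tab$cluster_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  structure(tab,
            class = c("cluster_table", "data.frame"),
            forming_cutoff = cutoff, connectivity = connectivity,
            df = df, kind = kind, clusters = comps)
}

#' Decompose a statistic map into supra-threshold clusters
#'
#' Converts the cluster-forming p threshold to a statistic cutoff (upper
#' tail of the t or F reference distribution), keeps voxels strictly above
#' the cutoff, and labels connected components. An empty table (no
#' supra-threshold voxels) is a valid result, not an error.
#'
#' @param stat_map a `stat_map` from [fit_voxelwise_t()] or [rm_anova_f()].
#' @param forming_threshold_p uncorrected per-voxel p cutoff.
#' @param connectivity 6, 18 or 26.
#' @return a `cluster_table` data frame (columns `cluster_id`, `size`,
#'   `peak_x/y/z` in mm, `peak_stat`, `peak_z_score`), with the member
#'   voxel indices attached as attribute `"clusters"`.
#' @export
label_clusters <- function(stat_map, forming_threshold_p = 0.005, connectivity = 18) {
  cutoff <- .forming_cutoff(stat_map$kind, stat_map$df, forming_threshold_p)
  vals <- as.vector(stat_map$values)
  supra <- which(!is.na(vals) & vals > cutoff)
  comps <- .label_components(supra, stat_map$grid$shape, connectivity)
  .cluster_table_from_comps(comps, vals, stat_map$grid, cutoff, connectivity,
                            stat_map$df, stat_map$kind)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("cluster_table: %d cluster(s), forming cutoff %.3f (%s), connectivity %d\n",
              nrow(x), attr(x, "forming_cutoff"), attr(x, "kind"),
              attr(x, "connectivity")))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a cluster table as CSV with a JSON sidecar
#'
#' @param tab a `cluster_table`.
#' @param path CSV output path; a `.json` sidecar recording the forming
#'   cutoff, connectivity, permutation count and seed (when present) is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  side <- list(forming_cutoff = attr(tab, "forming_cutoff"),
               connectivity = attr(tab, "connectivity"),
               df = attr(tab, "df"), kind = attr(tab, "kind"),
               n_permutations = attr(tab, "n_permutations"),
               seed = attr(tab, "seed"))
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
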