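# Independent oracles, written as directly as possible from definitions and
# kept separate from the implementation paths they check.

# Exhaustive connected-component enumeration on a 24-2 map by iterative
# label propagation over the full pairwise-adjacency matrix.
oracle_clusters <- function(exam, rule, adjacency = 8, confine = TRUE) {
  grid <- build_grid_242()
  abn <- !grid$blind_spot & !is.na(exam$pd) & exam$pd >= rule$abnormal_min
  idx <- which(abn)
  if (!length(idx)) return(list())
  dx <- abs(outer(grid$x[idx], grid$x[idx], `-`))
  dy <- abs(outer(grid$y[idx], grid$y[idx], `-`))
  adj <- if (adjacency == 8) dx <= 6 & dy <= 6 else
    (dx == 6 & dy == 0) | (dx == 0 & dy == 6)
  if (confine)
    adj <- adj & outer(grid$hemifield[idx], grid$hemifield[idx], `==`)
  diag(adj) <- TRUE
  lab <- seq_along(idx)
  repeat {
    new_lab <- vapply(seq_along(idx), function(i) min(lab[adj[i, ]]),
                      numeric(1))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  comps <- unname(split(idx, lab))
  comps <- Filter(function(co)
    length(co) >= rule$min_size &&
      sum(exam$pd[co] >= rule$strict_min) >= rule$strict_count, comps)
  lapply(comps, sort)
}

# cluster index sets as canonical sorted strings, for set comparison
cluster_key <- function(clusters)
  sort(vapply(clusters, function(co) paste(sort(co), collapse = ","),
              character(1)))
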