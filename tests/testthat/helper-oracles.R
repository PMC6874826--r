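# Shared helpers: random geometry, a brute-force assignment oracle, and small
# scene shortcuts.

random_box <- function(max_xy = 500, max_wh = 200) {
  x <- runif(1, 0, max_xy); y <- runif(1, 0, max_xy)
  box(x, y, x + runif(1, 1, max_wh), y + runif(1, 1, max_wh))
}

random_box_matrix <- function(n, ...) {
  do.call(rbind, replicate(n, random_box(...), simplify = FALSE))
}

# Exhaustive-enumeration oracle for the constrained assignment problem:
# minimizes total -IOU over all one-to-one assignments, enforcing
# iou > min_iou directly (a pair at or below the floor is simply left out of
# the assignment). Returns the optimal total cost.
brute_force_assignment_cost <- function(ious, min_iou = 0.1) {
  nd <- nrow(ious); nt <- ncol(ious)
  best <- 0 # empty assignment is feasible
  # enumerate assignments for each subset/ordering of detections to trackers
  recurse <- function(j, used, cost) {
    if (j > nd) {
      best <<- min(best, cost)
      return(invisible())
    }
    # option: leave detection j unassigned
    recurse(j + 1L, used, cost)
    for (k in seq_len(nt)) {
      if (!used[k] && ious[j, k] > min_iou)
        recurse(j + 1L, replace(used, k, TRUE), cost - ious[j, k])
    }
  }
  recurse(1L, rep(FALSE, nt), 0)
  best
}

# Total -IOU cost realized by an associate() result.
association_cost <- function(assoc, ious) {
  if (nrow(assoc$matches) == 0L) return(0)
  -sum(ious[assoc$matches])
}

random_psd_matrix <- function(n) {
  a <- matrix(rnorm(n * n), n, n)
  crossprod(a) + diag(n) * 1e-6
}

small_scene <- function(n = 8, seed = 1, ...) {
  simulate_scene(scene_config(n_seedlings = n, seed = seed, ...))
}

expect_symmetric_psd <- function(P, tol = 1e-9) {
  expect_lt(max(abs(P - t(P))), tol)
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -tol)
}
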