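#' Default species pool
#'
#' Creates an ordered pool of distinct species labels. The simulated planting
#' experiment draws its mixtures from a pool of eight species by default.
#'
#' @param n Number of species (>= 2 for mixtures; 1 is allowed for
#'   monoculture layouts).
#' @param labels Optional character vector of labels; must be distinct.
#' @return Character vector of species labels.
#' @export
species_pool <- function(n = 8, labels = NULL) {
  if (is.null(labels)) labels <- paste0("sp", seq_len(n))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("species labels must be distinct")
  labels
}

#' Ordered species-mixture permutations
#'
#' Enumerates or samples ordered r-permutations of the species pool. Order is
#' meaningful: it decides which species occupies which template role in a
#' planting design, so `c("a","b")` and `c("b","a")` are distinct mixtures.
#'
#' @param pool Character vector of species labels (see [species_pool()]).
#' @param richness Number of species per mixture, r.
#' @param count `"all"` to enumerate every ordered permutation, or an integer
#'   number of distinct permutations to sample uniformly without replacement.
#' @param seed Integer seed controlling the sample (ignored for `"all"`).
#' @return List of character vectors, each of length `richness`.
#' @examples
#' length(mixture_permutations(species_pool(8), 2))  # 56
#' @export
mixture_permutations <- function(pool, richness, count = "all", seed = NULL) {
  stopifnot(richness >= 1, richness <= length(pool))
  all_perms <- .ordered_permutations(length(pool), richness)
  n_all <- nrow(all_perms)
  if (identical(count, "all")) {
    idx <- seq_len(n_all)
  } else {
    count <- as.integer(count)
    if (count > n_all) {
      stop(sprintf("count = %d exceeds the %d ordered %d-permutations of a %d-species pool",
                   count, n_all, richness, length(pool)))
    }
    idx <- with_seed(seed, sample.int(n_all, count))
  }
  lapply(idx, function(i) pool[all_perms[i, ]])
}

# all ordered r-permutations of 1..n as an (nPr) x r integer matrix
.ordered_permutations <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  sub <- .ordered_permutations(n, r - 1)
  out <- vector("list", n)
  for (first in seq_len(n)) {
    rest <- sub[apply(sub != first, 1, all), , drop = FALSE]
    # relabel is unnecessary: sub already enumerates over 1..n
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' Neighbourhood specification for grid adjacency
#'
#' @param rule `"rook"` for the 4 orthogonally adjacent cells (direct
#'   neighbours; the default used by the heterogeneity null model) or
#'   `"moore"` for the 8 surrounding cells (used by the growth model).
#'   Adjacency is truncated at grid edges: under `"moore"` edge and corner
#'   trees have 5 and 3 neighbours, under `"rook"` 3 and 2.
#' @return Object of class `"neighborhood"` holding the row/column offsets.
#' @export
neighborhood <- function(rule = c("rook", "moore")) {
  rule <- match.arg(rule)
  offs <- switch(rule,
    rook  = cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L)),
    moore = {
      g <- expand.grid(dr = -1:1, dc = -1:1)
      as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
    })
  structure(list(rule = rule, offsets = offs), class = "neighborhood")
}

#' Construct a planting layout
#'
#' Assigns one species to each position of the 16 x 16 planting grid (1 m
#' spacing, 225 m2 plot) with equal abundance: each of the r species occupies
#' exactly 256/r positions. Template designs map the mixture's species order
#' onto fixed geometric roles; `"random"` is a seeded uniform shuffle.
#'
#' Templates: `block` partitions the grid into r compact rectangles (two
#' 8 x 16 halves for r = 2, four 8 x 8 quadrants for r = 4, two rows of four
#' 8 x 4 rectangles for r = 8); `single_line` assigns one species per column,
#' cycling the mixture order; `double_line` assigns two adjacent columns per
#' species; `miniblock` cycles species row-major over the 4 x 4 grid of 4 x 4
#' sub-squares.
#'
#' @param mixture Character vector of distinct species (ordered).
#' @param design One of `"block"`, `"miniblock"`, `"double_line"`,
#'   `"single_line"`, `"random"`.
#' @param seed Integer seed (used by `"random"` only).
#' @param n_grid Grid side length (default 16).
#' @return Object of class `"layout"`: list with `grid` (character matrix),
#'   `design`, `mixture`, `spacing` (m), `plot_area` (m2), `seed`.
#' @export
make_layout <- function(mixture, design = c("block", "miniblock", "double_line",
                                            "single_line", "random"),
                        seed = NULL, n_grid = 16L) {
  design <- match.arg(design)
  mixture <- as.character(mixture)
  if (anyDuplicated(mixture)) stop("mixture species must be distinct")
  r <- length(mixture)
  n_trees <- n_grid * n_grid
  if (n_trees %% r != 0)
    stop(sprintf("richness %d does not divide %d trees evenly; equal abundance impossible",
                 r, n_trees))
  grid <- switch(design,
    block       = .layout_block(mixture, n_grid),
    miniblock   = .layout_miniblock(mixture, n_grid),
    double_line = .layout_lines(mixture, n_grid, width = 2L),
    single_line = .layout_lines(mixture, n_grid, width = 1L),
    random      = .layout_random(mixture, n_grid, seed))
  .new_layout(grid, design, mixture, seed)
}

.new_layout <- function(grid, design, mixture, seed = NULL) {
  structure(list(grid = grid, design = design, mixture = mixture,
                 spacing = 1, plot_area = 225, seed = seed),
            class = "layout")
}

.layout_block <- function(mixture, n_grid) {
  r <- length(mixture)
  br <- if (r == 1) 1L else 2L            # rows of blocks
  bc <- r %/% br                          # columns of blocks
  if (n_grid %% bc != 0 || n_grid %% br != 0)
    stop(sprintf("no compact block partition of a %d x %d grid into %d rectangles",
                 n_grid, n_grid, r))
  h <- n_grid %/% br; w <- n_grid %/% bc
  grid <- matrix(NA_character_, n_grid, n_grid)
  k <- 1L
  for (i in seq_len(br)) for (j in seq_len(bc)) {
    grid[(i - 1L) * h + seq_len(h), (j - 1L) * w + seq_len(w)] <- mixture[k]
    k <- k + 1L
  }
  grid
}

.layout_lines <- function(mixture, n_grid, width) {
  r <- length(mixture)
  band <- (ceiling(seq_len(n_grid) / width) - 1L) %% r + 1L
  counts <- tabulate(band, r)
  if (length(unique(counts)) != 1L)
    stop(sprintf("%d-wide lines of %d species do not tile %d columns evenly",
                 width, r, n_grid))
  matrix(mixture[band], n_grid, n_grid, byrow = TRUE)
}

.layout_miniblock <- function(mixture, n_grid, block = 4L) {
  r <- length(mixture)
  nb <- n_grid %/% block
  if (n_grid %% block != 0) stop("grid not divisible into mini-blocks")
  if ((nb * nb) %% r != 0)
    stop(sprintf("%d mini-blocks cannot be shared evenly among %d species", nb * nb, r))
  grid <- matrix(NA_character_, n_grid, n_grid)
  k <- 0L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    grid[(i - 1L) * block + seq_len(block), (j - 1L) * block + seq_len(block)] <-
      mixture[k %% r + 1L]
    k <- k + 1L
  }
  grid
}

.layout_random <- function(mixture, n_grid, seed) {
  vec <- rep(mixture, each = n_grid * n_grid / length(mixture))
  matrix(with_seed(seed, sample(vec)), n_grid, n_grid)
}

#' @export
print.layout <- function(x, ...) {
  cat(sprintf("<layout> %s design, %d species (%s), %d x %d grid, %g m spacing\n",
              x$design, length(x$mixture), paste(x$mixture, collapse = ", "),
              nrow(x$grid), ncol(x$grid), x$spacing))
  invisible(x)
}

#' Species spatial heterogeneity against the hypergeometric null
#'
#' For each tree i, counts its conspecific neighbours N(i) under the
#' adjacency rule and compares them with the expectation under random
#' placement, where the neighbour composition follows a hypergeometric
#' distribution. With M_s trees of tree i's species among T trees total and
#' n_i actual neighbours, the conspecific expectation is
#' E\[X_i\] = n_i (M_s - 1) / (T - 1). The heterogeneity score is
#' H = sum_i (N(i) - E\[X_i\]): near 0 for random mixing, large and positive
#' for clustered (block-like) plantings, 0 exactly for a monoculture.
#'
#' @param layout A [make_layout()] object.
#' @param nb A [neighborhood()]; default rook (4 direct neighbours).
#' @param expectation `"conspecific"` (default) uses the conspecific-neighbour
#'   expectation above; `"heterospecific"` uses n_i (T - M_s) / (T - 1), the
#'   literal heterospecific count expectation. The two differ by a constant
#'   per layout class, so differences of H between designs are unaffected.
#' @return Object of class `"heterogeneity_score"`: list with `H` (scalar),
#'   `N` (matrix of conspecific neighbour counts), `E` (matrix of null
#'   expectations), `n` (matrix of neighbour counts) and `M` (named species
#'   abundances).
#' @export
heterogeneity <- function(layout, nb = neighborhood("rook"),
                          expectation = c("conspecific", "heterospecific")) {
  expectation <- match.arg(expectation)
  grid <- layout$grid
  T_ <- length(grid)
  M <- table(grid)
  cnt <- .neighbor_counts(grid, nb)
  M_i <- matrix(as.vector(M)[match(grid, names(M))], nrow(grid), ncol(grid))
  E <- if (expectation == "conspecific") {
    cnt$n * (M_i - 1) / (T_ - 1)
  } else {
    cnt$n * (T_ - M_i) / (T_ - 1)
  }
  structure(list(H = sum(cnt$N - E), N = cnt$N, E = E, n = cnt$n,
                 M = M, expectation = expectation, rule = nb$rule),
            class = "heterogeneity_score")
}

#' @export
print.heterogeneity_score <- function(x, ...) {
  cat(sprintf("<heterogeneity> H = %.2f (%s adjacency, %s expectation)\n",
              x$H, x$rule, x$expectation))
  invisible(x)
}

# per-cell conspecific neighbour count N and neighbour count n, by shifting
.neighbor_counts <- function(grid, nb) {
  nr <- nrow(grid); nc <- ncol(grid)
  N <- matrix(0L, nr, nc); n <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(nb$offsets))) {
    dr <- nb$offsets[k, 1]; dc <- nb$offsets[k, 2]
    rows <- seq_len(nr); cols <- seq_len(nc)
    rsrc <- rows + dr; csrc <- cols + dc
    rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
    if (!any(rok) || !any(cok)) next
    tgt_r <- rows[rok]; tgt_c <- cols[cok]
    same <- grid[tgt_r, tgt_c, drop = FALSE] ==
      grid[rsrc[rok], csrc[cok], drop = FALSE]
    N[tgt_r, tgt_c] <- N[tgt_r, tgt_c] + same
    n[tgt_r, tgt_c] <- n[tgt_r, tgt_c] + 1L
  }
  list(N = N, n = n)
}

#' Gradient of layouts from block to random
#'
#' Builds `levels` layouts whose heterogeneity scores are approximately evenly
#' spaced between H(block) and 0 (the null expectation of a random layout).
#' Candidates are produced by chains of cumulative random position swaps
#' applied to the block layout; for each evenly spaced target H the candidate
#' nearest in H is kept. Level 1 is the block layout itself.
#'
#' @param mixture Ordered species vector.
#' @param levels Number of gradient levels (>= 2; default 8).
#' @param seed Integer seed for the swap chains.
#' @param n_chains Number of independent swap chains (default 50).
#' @param max_swaps Swaps per chain (default 2000).
#' @param nb Adjacency for H (default rook).
#' @return List of `levels` layouts, each carrying its `H` and design label
#'   `gradient_1` ... `gradient_<levels>`.
#' @export
make_heterogeneity_gradient <- function(mixture, levels = 8L, seed = NULL,
                                        n_chains = 50L, max_swaps = 2000L,
                                        nb = neighborhood("rook")) {
  stopifnot(levels >= 2)
  block <- make_layout(mixture, "block")
  H_block <- heterogeneity(block, nb)$H
  targets <- seq(H_block, 0, length.out = levels)
  best_grid <- vector("list", levels)
  best_err <- rep(Inf, levels)
  best_grid[[1]] <- block$grid; best_err[1] <- 0
  with_seed(seed, {
    n_cell <- length(block$grid)
    for (chain in seq_len(n_chains)) {
      g <- block$grid
      for (k in seq_len(max_swaps)) {
        ij <- sample.int(n_cell, 2L)
        tmp <- g[ij[1]]; g[ij[1]] <- g[ij[2]]; g[ij[2]] <- tmp
        Hk <- .H_quick(g, nb, mixture)
        err <- abs(Hk - targets)
        better <- which(err < best_err)
        better <- better[better > 1L]       # level 1 stays the exact block
        for (lv in better) { best_err[lv] <- err[lv]; best_grid[[lv]] <- g }
      }
    }
  })
  lapply(seq_len(levels), function(lv) {
    lay <- .new_layout(best_grid[[lv]], sprintf("gradient_%d", lv), mixture, seed)
    lay$H <- heterogeneity(lay, nb)$H
    lay$H_target <- targets[lv]
    lay
  })
}

# H without building the score object (hot loop of the gradient search)
.H_quick <- function(grid, nb, mixture) {
  cnt <- .neighbor_counts(grid, nb)
  T_ <- length(grid)
  M_i <- matrix((T_ / length(mixture)), nrow(grid), ncol(grid))  # equal abundance
  sum(cnt$N - cnt$n * (M_i - 1) / (T_ - 1))
}
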