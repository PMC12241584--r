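# independent oracles, kept deliberately naive

# heterogeneity by an explicit double loop over all position pairs
brute_H <- function(layout, rule = "rook", expectation = "conspecific") {
  grid <- layout$grid
  nr <- nrow(grid); nc <- ncol(grid)
  pos <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  T_ <- nrow(pos)
  M <- table(grid)
  H <- 0
  for (i in seq_len(T_)) {
    Ni <- 0L; ni <- 0L
    for (j in seq_len(T_)) {
      if (i == j) next
      dr <- abs(pos$r[i] - pos$r[j]); dc <- abs(pos$c[i] - pos$c[j])
      adj <- if (rule == "rook") (dr + dc == 1) else (dr <= 1 && dc <= 1)
      if (!adj) next
      ni <- ni + 1L
      if (grid[pos$r[i], pos$c[i]] == grid[pos$r[j], pos$c[j]]) Ni <- Ni + 1L
    }
    Ms <- M[[grid[pos$r[i], pos$c[i]]]]
    E <- if (expectation == "conspecific") ni * (Ms - 1) / (T_ - 1)
         else ni * (T_ - Ms) / (T_ - 1)
    H <- H + Ni - E
  }
  H
}

# growth step re-implemented tree by tree
brute_growth_step <- function(B, layout, params) {
  nr <- nrow(B); nc <- ncol(B)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- layout$grid[r, c]
    inter <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      inter <- inter + params$alpha[s, layout$grid[rr, cc]] * B[rr, cc]^params$b
    }
    out[r, c] <- B[r, c] + params$beta[s] * B[r, c]^params$theta + inter
  }
  pmax(out, 1e-6)
}

# bare layout from a grid matrix (bypasses template construction)
grid_layout <- function(grid, design = "manual") {
  standlitter:::.new_layout(grid, design, unique(as.vector(grid)))
}

# small complete parameter set for map-level tests
toy_params <- function(pool) {
  r <- length(pool)
  list(
    litterfall = litterfall_params(
      b1 = setNames(rep(0.05, r), pool),
      b2 = setNames(rep(2, r), pool),
      b3 = setNames(rep(0.1, r), pool)),
    decomp = decomp_params(
      beta = setNames(seq(30, 50, length.out = r), pool),
      alpha = setNames(rep(2, r), pool),
      b4 = 0.01, b5 = 1, element = "C")
  )
}
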