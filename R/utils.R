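# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# metric stem positions of a layout: x = (col-1)*spacing, y = (row-1)*spacing,
# column-major order matching as.vector(grid)
tree_positions <- function(layout) {
  nr <- nrow(layout$grid); nc <- ncol(layout$grid)
  data.frame(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep((seq_len(nc) - 1) * layout$spacing, each = nr),
    y = rep((seq_len(nr) - 1) * layout$spacing, times = nc),
    species = as.vector(layout$grid),
    stringsAsFactors = FALSE
  )
}
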