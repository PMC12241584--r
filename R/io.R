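#' Write a layout to CSV with a JSON sidecar
#'
#' The CSV holds the 16 x 16 grid of species labels (no header); the sidecar
#' `<path>.json` records design, mixture, seed and the heterogeneity score.
#'
#' @param layout A [make_layout()] object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(design = layout$design, mixture = layout$mixture,
               seed = layout$seed, spacing = layout$spacing,
               plot_area = layout$plot_area,
               H = heterogeneity(layout)$H)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a layout written by [write_layout()]
#'
#' @param path CSV file path (sidecar `<path>.json` must exist).
#' @return A layout object.
#' @export
read_layout <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = ",",
                                      colClasses = "character"))
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lay <- .new_layout(grid, meta$design, meta$mixture, meta$seed)
  lay$spacing <- meta$spacing
  lay$plot_area <- meta$plot_area
  lay
}

#' Read growth parameters from long-format CSV tables
#'
#' @param beta_path CSV with columns `species`, `beta`.
#' @param alpha_path CSV with columns `species_i`, `species_j`, `alpha`.
#' @param theta,b Allometric exponents.
#' @return A [growth_params()] object.
#' @export
read_growth_params <- function(beta_path, alpha_path, theta = 0.75, b = 0.75) {
  bt <- utils::read.csv(beta_path, stringsAsFactors = FALSE)
  at <- utils::read.csv(alpha_path, stringsAsFactors = FALSE)
  sp <- bt$species
  alpha <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  alpha[cbind(match(at$species_i, sp), match(at$species_j, sp))] <- at$alpha
  growth_params(stats::setNames(bt$beta, sp), alpha, theta, b)
}

#' Write a field dataset to CSV files
#'
#' Writes `trap_litter.csv`, `trap_trees.csv`, `bags.csv` and, when the
#' dataset carries a ground truth, `truth.json` (coefficients only) under
#' `dir`.
#'
#' @param dataset A [generate_field_dataset()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$litter, file.path(dir, "trap_litter.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$trees, file.path(dir, "trap_trees.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$bags, file.path(dir, "bags.csv"), row.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    jsonlite::write_json(list(
      litterfall = list(b1 = as.list(tr$litterfall$b1),
                        b2 = as.list(tr$litterfall$b2),
                        b3 = as.list(tr$litterfall$b3)),
      decomp_C = list(beta = as.list(tr$decomp_C$beta),
                      alpha = as.list(tr$decomp_C$alpha),
                      b4 = tr$decomp_C$b4, b5 = tr$decomp_C$b5),
      decomp_N = list(beta = as.list(tr$decomp_N$beta),
                      alpha = as.list(tr$decomp_N$alpha),
                      b4 = tr$decomp_N$b4, b5 = tr$decomp_N$b5)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a field dataset written by [write_field_dataset()]
#'
#' @param dir Directory holding the CSV files.
#' @return A `field_dataset` list (without ground truth).
#' @export
read_field_dataset <- function(dir) {
  structure(list(
    litter = utils::read.csv(file.path(dir, "trap_litter.csv"),
                             stringsAsFactors = FALSE),
    trees = utils::read.csv(file.path(dir, "trap_trees.csv"),
                            stringsAsFactors = FALSE),
    bags = utils::read.csv(file.path(dir, "bags.csv"),
                           stringsAsFactors = FALSE),
    truth = NULL), class = "field_dataset")
}
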