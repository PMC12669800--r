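#' Model configuration
#'
#' Builds the full hyperparameter set shared by featurization, encoders,
#' task heads, and training. Every value can be overridden; unknown names
#' are rejected so typos in config files fail loudly.
#'
#' Key parameters (units in parentheses):
#' \describe{
#'   \item{cutoff}{residue-graph contact cutoff between alpha-carbons (Å), 12.}
#'   \item{sigma}{width of the Gaussian radial basis distance encoding (Å), 1.}
#'   \item{lambda}{blend between node- and edge-similarity attention in the
#'     protein encoder, in \code{[0,1]}; 0.5.}
#'   \item{T}{number of encoder / heterogeneous-convolution layers, 3.}
#'   \item{k}{nearest neighbours per node in the interface graph, 6.}
#'   \item{h1...h6}{hidden widths: protein encoder (h1), surface projection
#'     (h2), drug encoder (h3), occurrence head (h4), site head (h5),
#'     affinity head (h6).}
#'   \item{heads}{attention heads in multi-head attention blocks, 4.}
#'   \item{focal_alpha, focal_gamma}{focal-loss positive-class weight and
#'     focusing exponent for site training, 0.75 / 2. The positive class is
#'     the rare one at realistic site imbalance, so alpha must up-weight it;
#'     see the methods vignette.}
#'   \item{pocket_radius}{fallback pocket rule: residues with any heavy atom
#'     within this distance (Å) of any ligand heavy atom, 10.}
#'   \item{pairwise}{pair set for the affinity head's pairwise aggregation:
#'     "edges" (interface-graph pairs) or "all".}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return an object of class \code{tribind_config} (a named list).
#' @examples
#' cfg <- model_config(lambda = 0.25)
#' cfg$lambda
#' @export
model_config <- function(...) {
  cfg <- list(
    h1 = 128L, h2 = 32L, h3 = 128L, h4 = 128L, h5 = 128L, h6 = 128L,
    lambda = 0.5, sigma = 1.0, T = 3L, k = 6L,
    heads = 4L, dropout = 0.1,
    focal_alpha = 0.75, focal_gamma = 2,
    lr = 1e-3, epochs = 300L, batch_size = 8L, seed = 1L,
    cutoff = 12, pocket_radius = 10,
    leaky_slope = 0.01,
    surface_probe = 1.4, surface_points = 40L, surface_fit_radius = 3.0,
    pairwise = "edges",
    patience = 20L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(ov)) cfg[[nm]] <- coerce_cfg(cfg[[nm]], ov[[nm]], nm)
  }
  if (cfg$lambda < 0 || cfg$lambda > 1) stop("lambda must lie in [0, 1]")
  if (cfg$T < 1) stop("T must be >= 1")
  hs <- unlist(cfg[c("h1", "h2", "h3", "h4", "h5", "h6")])
  if (any(hs <= 0)) stop("all hidden sizes must be positive")
  if (!cfg$pairwise %in% c("edges", "all")) {
    stop("pairwise must be 'edges' or 'all'")
  }
  structure(cfg, class = "tribind_config")
}

coerce_cfg <- function(default, value, key) {
  if (is.character(default)) {
    if (!is.character(value)) stop("config key '", key, "' must be character")
    return(value)
  }
  if (!is.numeric(value)) {
    stop("config key '", key, "' must be numeric, got ", class(value)[1])
  }
  if (is.integer(default)) as.integer(value) else as.numeric(value)
}

#' Desk-scale configuration profile
#'
#' The reduced-width profile used for CPU-scale training runs, examples and
#' the package's own verification experiments: hidden widths 32 (surface
#' projection 16), 2 attention heads, otherwise the standard defaults.
#' The architecture is identical to [model_config()]; only capacity
#' changes.
#'
#' @param ... further overrides, as in [model_config()].
#' @return a \code{tribind_config}.
#' @export
desk_config <- function(...) {
  model_config(h1 = 32L, h2 = 16L, h3 = 32L, h4 = 32L, h5 = 32L, h6 = 32L,
               heads = 2L, ...)
}

#' Load a configuration file
#'
#' Reads a flat key:value YAML file, fills unspecified keys with defaults,
#' then applies any programmatic overrides last.
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @param overrides named list applied after the file.
#' @return a \code{tribind_config}.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("config file must be a flat key: value mapping")
    vals <- raw
  }
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  do.call(model_config, vals)
}

#' @export
print.tribind_config <- function(x, ...) {
  cat("tribind model configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
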