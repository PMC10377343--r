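# Text serialisation of a trained bundle (JSON; models are flat arrays).
#
# Doubles are written as "%.17g" strings because JSON writers that print
# ~15 significant digits drop ULPs, and split thresholds must survive
# serialisation bit-exactly for reload-identical predictions.

num_pack <- function(x) sprintf("%.17g", as.numeric(x))
num_unpack <- function(x) as.numeric(unlist(x))

tree_to_list <- function(tr) {
  out <- list(feature = tr$feature, threshold = num_pack(tr$threshold),
              left = tr$left, right = tr$right, value = num_pack(tr$value),
              classify = tr$classify, n_class = tr$n_class)
  if (tr$classify) out$dist <- num_pack(as.vector(tr$dist))
  out
}

tree_from_list <- function(l) {
  out <- list(feature = as.integer(unlist(l$feature)),
              threshold = num_unpack(l$threshold),
              left = as.integer(unlist(l$left)),
              right = as.integer(unlist(l$right)),
              value = num_unpack(l$value), classify = isTRUE(l$classify),
              n_class = as.integer(l$n_class))
  if (out$classify)
    out$dist <- matrix(num_unpack(l$dist), ncol = out$n_class)
  out
}

#' Save / load a trained bundle
#'
#' The bundle is written to a directory as JSON files: the classifier and
#' regressor ensembles as flat tree arrays, the GP regressor's inducing
#' matrix and weights, the normalisation statistics and both feature
#' selections. Doubles are stored as 17-significant-digit strings, so a
#' reloaded bundle produces predictions identical to the original's.
#'
#' @param bundle a `trained_bundle`.
#' @param path directory to create.
#' @export
save_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f)
    jsonlite::write_json(x, file.path(path, f), auto_unbox = TRUE,
                         digits = NA, null = "null")
  cls <- bundle$classifier
  wj(list(alphas = num_pack(cls$alphas), classes = cls$classes, K = cls$K,
          trees = lapply(cls$trees, tree_to_list)), "classifier.json")
  wj(list(trees = lapply(bundle$regressor_b2$trees, tree_to_list)),
     "regressor_b2.json")
  g <- bundle$regressor_b1
  wj(list(X = num_pack(as.vector(g$X)), n_row = nrow(g$X),
          features = colnames(g$X), alpha = num_pack(g$alpha),
          beta = num_pack(g$beta), kernel_scale = num_pack(g$kernel_scale),
          signal_sd = num_pack(g$signal_sd),
          noise_sd = num_pack(g$noise_sd)), "regressor_b1.json")
  wj(list(mean = num_pack(bundle$norm$mean), sd = num_pack(bundle$norm$sd),
          dropped = bundle$norm$dropped, features = bundle$norm$features),
     "norm.json")
  pack_sel <- function(s)
    list(weights = num_pack(s$weights), names = names(s$weights),
         selected = s$selected, method = s$method, k = s$k)
  wj(list(classifier = pack_sel(bundle$selection_classifier),
          regressor = pack_sel(bundle$selection_regressor)),
     "selection.json")
  wj(list(cv = bundle$cv, cfg = unclass(bundle$cfg)), "meta.json")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  rj <- function(f) jsonlite::read_json(file.path(path, f),
                                        simplifyVector = TRUE,
                                        simplifyDataFrame = FALSE)
  cls <- rj("classifier.json")
  classifier <- structure(
    list(trees = lapply(cls$trees, tree_from_list),
         alphas = num_unpack(cls$alphas),
         classes = as.integer(cls$classes), K = as.integer(cls$K)),
    class = "adaboost_model")
  b2l <- rj("regressor_b2.json")
  b2 <- structure(list(trees = lapply(b2l$trees, tree_from_list)),
                  class = "bag_model")
  g <- rj("regressor_b1.json")
  Xg <- matrix(num_unpack(g$X), nrow = g$n_row)
  colnames(Xg) <- g$features
  b1 <- structure(list(X = Xg, alpha = num_unpack(g$alpha),
                       beta = num_unpack(g$beta),
                       kernel_scale = num_unpack(g$kernel_scale),
                       signal_sd = num_unpack(g$signal_sd),
                       noise_sd = num_unpack(g$noise_sd)),
                  class = "gpr_model")
  nrm <- rj("norm.json")
  feats <- unlist(nrm$features)
  norm <- structure(
    list(mean = setNames(num_unpack(nrm$mean), feats),
         sd = setNames(num_unpack(nrm$sd), feats),
         dropped = as.character(unlist(nrm$dropped)),
         features = feats),
    class = "norm_stats")
  sel <- rj("selection.json")
  mk_sel <- function(s) structure(
    list(weights = setNames(num_unpack(s$weights), unlist(s$names)),
         selected = as.integer(unlist(s$selected)),
         method = s$method, k = as.integer(s$k)),
    class = "selection_result")
  meta <- rj("meta.json")
  cfg <- meta$cfg
  cfg$bandpass <- as.numeric(unlist(cfg$bandpass))
  class(cfg) <- "pipeline_config"
  out <- list(classifier = classifier, regressor_b1 = b1, regressor_b2 = b2,
              norm = norm,
              selection_classifier = mk_sel(sel$classifier),
              selection_regressor = mk_sel(sel$regressor),
              cv = meta$cv, cfg = cfg)
  class(out) <- "trained_bundle"
  out
}
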