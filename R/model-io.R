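## JSON serialization of trained tree models. The layout is documented
## and stable: topology, kernel parameters, per-node SVMs (support ids,
## dual coefficients, bias, sigmoid calibration) and the sparse training
## feature vectors the kernel needs at prediction time.

#' Write a trained tree model to JSON
#'
#' @param model a `tree_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "profloc_tree_model",
    version = 1L,
    domain = model$spec$domain,
    tree = list(root = model$spec$root, nodes = model$spec$nodes,
                classes = model$spec$classes),
    params = list(k = model$params$k, theta = model$params$theta,
                  alphabet = paste(model$params$alphabet, collapse = "")),
    C = model$C,
    nodes = lapply(model$node_models, function(n)
      list(node_id = n$node_id, support_ids = n$support_ids,
           dual_coefs = n$dual_coefs, bias = n$bias,
           platt_a = n$platt_a, platt_b = n$platt_b)),
    training_features = lapply(model$training_features, function(f)
      list(k = f$k, kmers = names(f$counts),
           counts = unname(as.integer(f$counts)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tree model from JSON
#'
#' @param path path written by [write_model()].
#' @return A `tree_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  if (!identical(obj$format, "profloc_tree_model"))
    stop("not a profloc model file: ", path, call. = FALSE)
  spec <- tree_spec(obj$domain, obj$tree$nodes, obj$tree$root,
                    classes = obj$tree$classes)
  params <- kernel_params(obj$params$k, obj$params$theta,
                          strsplit(obj$params$alphabet, "")[[1]],
                          allow_large_k = TRUE)
  node_models <- lapply(obj$nodes, function(n)
    structure(list(node_id = n$node_id,
                   support_ids = as.character(n$support_ids),
                   dual_coefs = as.numeric(n$dual_coefs),
                   bias = as.numeric(n$bias),
                   platt_a = as.numeric(n$platt_a),
                   platt_b = as.numeric(n$platt_b)),
              class = "node_model"))
  fvs <- lapply(obj$training_features, function(f)
    new_kmer_fv(stats::setNames(as.integer(f$counts),
                                as.character(f$kmers)),
                f$k))
  structure(list(spec = spec, params = params, C = as.numeric(obj$C),
                 node_models = node_models, training_features = fvs,
                 cache = new.env(parent = emptyenv())),
            class = "tree_model")
}
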