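## Decision-tree topology: a proper binary tree whose leaves are the
## localization classes of one domain of life. Topologies are data, not
## code: they ship as editable JSON configs (see inst/extdata).

#' Construct and validate a tree topology
#'
#' @param domain domain of life; fixes the expected leaf set unless
#'   `classes` is given explicitly (programmatic use, e.g. toy trees).
#' @param nodes data.frame with columns `id`, `left`, `right`; a child
#'   entry naming another node id is an internal edge, anything else is a
#'   leaf class label.
#' @param root id of the root node.
#' @param classes leaf class set to validate against; defaults to
#'   [domain_classes()] of `domain`.
#' @return Object of class `tree_spec`.
#' @export
tree_spec <- function(domain, nodes, root, classes = NULL) {
  domain <- match_domain(domain)
  if (is.null(classes)) classes <- domain_classes(domain)
  nodes <- data.frame(id = as.character(nodes$id),
                      left = as.character(nodes$left),
                      right = as.character(nodes$right),
                      stringsAsFactors = FALSE)
  ids <- nodes$id
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  if (length(intersect(ids, classes)))
    stop("node ids may not collide with class labels", call. = FALSE)
  if (!root %in% ids) stop("root id not among nodes", call. = FALSE)
  children <- c(nodes$left, nodes$right)
  if (anyDuplicated(children))
    stop("a child appears under two parents (not a tree)", call. = FALSE)
  if (root %in% children) stop("root appears as a child", call. = FALSE)
  internal_children <- children[children %in% ids]
  if (length(internal_children) != length(ids) - 1L)
    stop("disconnected or malformed tree", call. = FALSE)
  leaves <- setdiff(children, ids)
  if (anyDuplicated(leaves)) stop("duplicate leaf label", call. = FALSE)
  if (!setequal(leaves, classes))
    stop("leaf set does not match the class set; missing: ",
         paste(setdiff(classes, leaves), collapse = ", "),
         "; extra: ", paste(setdiff(leaves, classes), collapse = ", "),
         call. = FALSE)
  structure(list(domain = domain, nodes = nodes, root = root,
                 classes = sort(classes)),
            class = "tree_spec")
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("<tree_spec>", x$domain, "-", nrow(x$nodes), "internal nodes,",
      length(x$classes), "leaf classes\n")
  invisible(x)
}

is_internal <- function(spec, child) child %in% spec$nodes$id

node_row <- function(spec, id) spec$nodes[spec$nodes$id == id, ]

#' Leaf classes under a child (node id or leaf label)
#'
#' @param spec a `tree_spec`.
#' @param child a node id or a leaf class label.
#' @return Character vector of class labels.
#' @export
leaves_under <- function(spec, child) {
  if (!is_internal(spec, child)) return(child)
  r <- node_row(spec, child)
  c(leaves_under(spec, r$left), leaves_under(spec, r$right))
}

#' Load a tree topology from a JSON config
#'
#' Layout: `{"domain": ..., "root": ..., "nodes": [{"id", "left",
#' "right"}, ...]}`. A child string that names another node id is an
#' internal edge; any other string is a leaf class label. The leaf set
#' must equal the class set of the stated domain exactly.
#'
#' @param path path to the JSON file.
#' @return A validated `tree_spec`.
#' @export
load_tree_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("domain", "root", "nodes") %in% names(cfg)))
    stop("tree config must have fields domain, root, nodes", call. = FALSE)
  tree_spec(cfg$domain, cfg$nodes, cfg$root)
}

#' Default shipped tree topology for a domain
#'
#' Loads the package's editable default config. The topologies follow
#' the cell's sorting anatomy (secretory pathway split off first, then
#' membrane/soluble splits); they are a reasonable default, not a claim
#' about any externally trained tree.
#'
#' @inheritParams domain_classes
#' @return A `tree_spec`.
#' @export
default_tree_spec <- function(domain = c("eukaryota", "bacteria",
                                         "archaea")) {
  domain <- match.arg(domain)
  load_tree_spec(system.file("extdata",
                             paste0("tree_", domain, ".json"),
                             package = "profloc", mustWork = TRUE))
}

#' Serialize a tree topology to JSON
#'
#' @param spec a `tree_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_spec <- function(spec, path) {
  jsonlite::write_json(list(domain = spec$domain, root = spec$root,
                            nodes = spec$nodes),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
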