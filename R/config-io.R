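#' Read / write a pipeline configuration as JSON
#'
#' All hyperparameters of the Re-RX pipeline, including the network
#' seed, in one document: top-level \code{delta1}, \code{delta2},
#' \code{max_recursion_depth}, \code{use_continuous},
#' \code{tree_targets}, \code{min_subdivide_n}, and nested \code{net}
#' and \code{tree} blocks.  Missing fields take the package defaults.
#'
#' @param config a \code{rerx_config}.
#' @param path file path.
#' @export
write_rerx_config <- function(config, path) {
  out <- unclass(config)
  out$net <- unclass(out$net)
  out$tree <- unclass(out$tree)
  out$tree$max_depth <- if (is.finite(out$tree$max_depth))
    out$tree$max_depth else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_rerx_config
#' @export
read_rerx_config <- function(path) {
  raw <- jsonlite::read_json(path)
  pick <- function(lst, defaults) {
    args <- lst[intersect(names(lst), names(defaults))]
    utils::modifyList(defaults, args)
  }
  net <- do.call(net_config, pick(raw$net %||% list(),
                                  formals_defaults(net_config)))
  tree <- do.call(tree_config, pick(raw$tree %||% list(),
                                    formals_defaults(tree_config)))
  top <- raw[intersect(names(raw),
                       c("delta1", "delta2", "max_recursion_depth",
                         "use_continuous", "tree_targets",
                         "min_subdivide_n"))]
  do.call(rerx_config, c(top, list(net = net, tree = tree)))
}

formals_defaults <- function(f) {
  d <- as.list(formals(f))
  d <- d[!vapply(d, is.symbol, TRUE) & !vapply(d, is.call, TRUE)]
  d
}
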