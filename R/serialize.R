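#' Serialize RBM parameters or a classifier network as JSON
#'
#' Plain-text JSON containers for trained models: weight matrices are stored
#' row-wise with their dimensions, so files are portable and diff-able.
#' Numeric values are written in full precision.
#'
#' @param object An `rbm_parameters` or `dbn_network`.
#' @param path File path.
#' @return The reader returns the reconstructed object; writers return
#'   `path` invisibly.
#' @export
write_model_json <- function(object, path) {
  obj <- if (inherits(object, "rbm_parameters")) {
    list(type = "rbm_parameters", visible_family = object$visible_family,
         dim = dim(object$W), W = as.numeric(t(object$W)),
         b_vis = object$b_vis, b_hid = object$b_hid,
         training_log = attr(object, "training_log"))
  } else if (inherits(object, "dbn_network")) {
    list(type = "dbn_network", n_input = object$n_input,
         classes = object$classes,
         layers = lapply(object$layers, function(l) {
           list(dim = dim(l$W), W = as.numeric(t(l$W)), b = l$b)
         }),
         out = list(dim = dim(object$W_out), W = as.numeric(t(object$W_out)),
                    b = object$b_out),
         training_log = attr(object, "training_log"))
  } else {
    stop("unsupported object class: ", paste(class(object), collapse = "/"))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  unpack <- function(w, d) matrix(w, d[1], d[2], byrow = TRUE)
  if (identical(obj$type, "rbm_parameters")) {
    out <- rbm_parameters(unpack(obj$W, obj$dim), obj$b_vis, obj$b_hid,
                          obj$visible_family)
  } else if (identical(obj$type, "dbn_network")) {
    out <- structure(
      list(layers = lapply(obj$layers, function(l) {
        list(W = unpack(l$W, l$dim), b = l$b)
      }),
      W_out = unpack(obj$out$W, obj$out$dim), b_out = obj$out$b,
      n_input = obj$n_input, classes = obj$classes),
      class = "dbn_network")
  } else {
    stop("unrecognized model container: ", path)
  }
  if (!is.null(obj$training_log)) {
    attr(out, "training_log") <- obj$training_log
  }
  out
}
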