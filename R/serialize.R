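# Versioned JSON serialization for trained models.

.SERIAL_VERSION <- "1.0"

#' Serialize a trained model to JSON
#'
#' Writes a versioned JSON document holding every coefficient and
#' hyperparameter needed for exact reload; [model_from_json()] restores a
#' model whose predictions are identical.
#'
#' @param model An `adaboost_model`, `svm_model` or `mlp_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  type <- class(model)[1]
  stopifnot(type %in% c("adaboost_model", "svm_model", "mlp_model"))
  payload <- unclass(model)
  if (type == "adaboost_model") payload$history <- NULL
  doc <- list(format = "tonguecolor-model", version = .SERIAL_VERSION,
              type = type, payload = payload)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

.restore_tree <- function(node) {
  node$leaf <- isTRUE(node$leaf)
  if (!node$leaf) {
    node$left <- .restore_tree(node$left)
    node$right <- .restore_tree(node$right)
  }
  node
}

#' Restore a model serialized with [model_to_json()]
#'
#' @param json A JSON string or path to a JSON file.
#' @return The restored model object.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json)) json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(doc$format, "tonguecolor-model"))
    stop("not a serialized tonguecolor model")
  p <- doc$payload
  if (doc$type == "adaboost_model") {
    p$rounds <- lapply(p$rounds, function(r)
      list(tree = .restore_tree(r$tree), alpha = r$alpha))
  } else if (doc$type == "svm_model") {
    p$x <- matrix(unlist(p$x), nrow = length(p$alpha))
    if (!is.null(p$std)) {
      p$std$center <- as.numeric(p$std$center)
      p$std$scale <- as.numeric(p$std$scale)
    }
  } else if (doc$type == "mlp_model") {
    p$W1 <- matrix(unlist(p$W1), nrow = p$hidden_units)
    p$W2 <- matrix(unlist(p$W2), nrow = 2)
    if (!is.null(p$std)) {
      p$std$center <- as.numeric(p$std$center)
      p$std$scale <- as.numeric(p$std$scale)
    }
  }
  structure(p, class = doc$type)
}
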