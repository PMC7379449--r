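# JSON (de)serialization of model objects. Schema "petlat-model/1":
#   { "schema": "petlat-model/1", "type": "tree" | "linear", ... }
# Tree nodes nest as {feature, threshold, left, right} with {class, ...}
# leaves; linear models carry the Left-class intercept and coefficient map
# (the Right-class score is its exact negation and is never stored).

node_to_list <- function(node) {
  if (node$leaf) {
    list(class = node$class, n = node$n)
  } else {
    list(
      feature = node$feature, threshold = node$threshold, n = node$n,
      left = node_to_list(node$left), right = node_to_list(node$right)
    )
  }
}

node_from_list <- function(x) {
  if (!is.null(x$class)) {
    if (!x$class %in% tle_classes()) {
      abort(paste0("Unknown leaf class `", x$class, "` in model JSON."))
    }
    return(list(leaf = TRUE, class = x$class, n = x$n %||% 0L,
                counts = c(0L, 0L), errors = 0L))
  }
  if (is.null(x$feature) || is.null(x$threshold) ||
      is.null(x$left) || is.null(x$right)) {
    abort("Malformed tree node in model JSON.")
  }
  if (!x$feature %in% pair_names()) {
    abort(paste0("Unknown region pair `", x$feature, "` in model JSON."))
  }
  list(
    leaf = FALSE, feature = x$feature, threshold = as.numeric(x$threshold),
    n = x$n %||% 0L, counts = c(0L, 0L),
    left = node_from_list(x$left), right = node_from_list(x$right)
  )
}

#' Serialize a model to JSON
#'
#' Writes an `ai_tree` or `ai_linear` model as a human-readable,
#' versioned JSON document; [parse_model()] restores an equivalent model
#' (round-trip predictions are identical).
#'
#' @param model An `ai_tree` or `ai_linear`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
serialize_model <- function(model, path = NULL) {
  payload <- if (inherits(model, "ai_tree")) {
    list(
      schema = "petlat-model/1", type = "tree",
      tree = node_to_list(model$node),
      n = model$n, rendered = strsplit(format(model), "\n")[[1]]
    )
  } else if (inherits(model, "ai_linear")) {
    list(
      schema = "petlat-model/1", type = "linear",
      intercept = model$intercept,
      coefficients = as.list(model$coefficients),
      iterations = model$iterations,
      n = model$n, rendered = strsplit(format(model), "\n")[[1]]
    )
  } else {
    abort("`model` must be an ai_tree or ai_linear.")
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Parse a model from JSON
#'
#' @param json JSON text or a path to a JSON file produced by
#'   [serialize_model()].
#' @return An `ai_tree` or `ai_linear`.
#' @export
parse_model <- function(json) {
  txt <- if (length(json) == 1 && !grepl("[{]", json) && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  x <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) abort(paste0("Malformed model JSON: ", conditionMessage(e)))
  )
  if (!identical(x$schema, "petlat-model/1")) {
    abort("Unsupported or missing model schema (expected petlat-model/1).")
  }
  if (identical(x$type, "tree")) {
    node <- node_from_list(x$tree)
    structure(
      list(node = node, classes = tle_classes(),
           features = tree_features(node),
           params = list(parsed = TRUE), n = x$n %||% 0L,
           class_counts = setNames(c(0L, 0L), tle_classes())),
      class = "ai_tree"
    )
  } else if (identical(x$type, "linear")) {
    coefs <- unlist(x$coefficients) %||% setNames(numeric(0), character(0))
    unknown <- setdiff(names(coefs), pair_names())
    if (length(unknown) > 0) {
      abort(paste0("Unknown region pair(s) in model JSON: ",
                   paste(unknown, collapse = ", ")))
    }
    new_linear_model(
      intercept = as.numeric(x$intercept), coefficients = coefs,
      n = x$n %||% 0L, iterations = x$iterations %||% NA_integer_,
      params = list(parsed = TRUE)
    )
  } else {
    abort("Model JSON `type` must be \"tree\" or \"linear\".")
  }
}
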