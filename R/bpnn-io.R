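BPNN_SCHEMA_VERSION <- "1.0"

#' Save / load a fitted network as versioned JSON
#'
#' The JSON document carries a schema version, the layer dimensions, all
#' weights (row-major, 17 significant digits so doubles round-trip exactly),
#' the input scaler, the target scale, and the training-state
#' hyperparameters. `bpnn_load()` refuses documents with a different schema
#' version.
#'
#' @param model A fitted [bpnn_train()] model.
#' @param path File path.
#' @return `bpnn_save()` returns `model` invisibly; `bpnn_load()` returns the
#'   restored `bpnn` object.
#' @export
bpnn_save <- function(model, path) {
  stopifnot(inherits(model, "bpnn"))
  doc <- list(
    schema_version = BPNN_SCHEMA_VERSION,
    scale_name = model$scale_name,
    target_range = model$target_range,
    n_in = model$n_in, n_hidden = model$n_hidden,
    W1 = as.vector(t(model$W1)),   # row-major
    b1 = model$b1, W2 = as.vector(model$W2), b2 = model$b2,
    feature_names = model$feature_names,
    input_center = unname(model$input_center),
    input_scale = unname(model$input_scale),
    train_state = model$train_state,
    seed = model$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(model)
}

#' @rdname bpnn_save
#' @export
bpnn_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != BPNN_SCHEMA_VERSION)
    abort_semg(sprintf("model schema version %s does not match supported %s.",
                       doc$schema_version %||% "<missing>", BPNN_SCHEMA_VERSION),
               "version")
  fn <- doc$feature_names
  structure(list(
    n_in = as.integer(doc$n_in), n_hidden = as.integer(doc$n_hidden),
    W1 = matrix(doc$W1, doc$n_hidden, doc$n_in, byrow = TRUE),
    b1 = doc$b1, W2 = doc$W2, b2 = doc$b2,
    input_center = stats::setNames(doc$input_center, fn),
    input_scale = stats::setNames(doc$input_scale, fn),
    target_range = doc$target_range,
    scale_name = if (is.null(doc$scale_name)) NA_character_ else doc$scale_name,
    feature_names = fn,
    train_state = as.list(doc$train_state),
    seed = doc$seed
  ), class = "bpnn")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the weights of a fitted network
#'
#' @param x A `bpnn` model.
#' @param ... Unused.
#' @return A tibble with one row per weight: `layer` (`"hidden"` or
#'   `"output"`), `from` (input feature or hidden unit), `to`, `estimate`.
#' @exportS3Method generics::tidy
tidy.bpnn <- function(x, ...) {
  inputs <- x$feature_names %||% paste0("x", seq_len(x$n_in))
  hidden <- paste0("h", seq_len(x$n_hidden))
  dplyr::bind_rows(
    tidyr::expand_grid(to = hidden, from = inputs) |>
      dplyr::mutate(layer = "hidden",
                    estimate = as.vector(t(x$W1))),
    tibble::tibble(layer = "hidden", from = "(bias)", to = hidden,
                   estimate = x$b1),
    tibble::tibble(layer = "output", from = hidden, to = "score",
                   estimate = as.vector(x$W2)),
    tibble::tibble(layer = "output", from = "(bias)", to = "score",
                   estimate = x$b2)
  ) |>
    dplyr::select("layer", "from", "to", "estimate")
}

#' One-row training summary of a fitted network
#'
#' @param x A `bpnn` model.
#' @param ... Unused.
#' @return A tibble with the regularization hyperparameters (`alpha`, `beta`,
#'   effective parameter count `gamma`), errors, sizes and stop reason.
#' @exportS3Method generics::glance
glance.bpnn <- function(x, ...) {
  st <- x$train_state
  tibble::tibble(
    n_in = x$n_in, n_hidden = x$n_hidden, n_params = st$n_params,
    n_cases = st$n_cases, n_iter = st$n_iter,
    alpha = st$alpha, beta = st$beta, gamma = st$gamma,
    E_D = st$E_D, E_W = st$E_W, stop_reason = st$stop_reason
  )
}
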