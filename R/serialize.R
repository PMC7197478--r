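MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a trained predictor to versioned JSON
#'
#' Writes the phase grid, per-gene trend arrays (training angles, fitted
#' values, sigma, lambda, PVE), the normalization provenance and the
#' training manifest, with a `schema_version` field, at full numeric
#' precision so that deserialization reproduces predictions exactly.
#'
#' @param model A `"trained_predictor"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  if (!inherits(model, "trained_predictor"))
    stop("model must be a trained_predictor")
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    grid = list(K = model$grid$K),
    normalization = model$normalization,
    manifest = model$manifest,
    genes = lapply(model$genes, function(g) {
      tr <- model$trends[[g]]
      list(gene_id = g, train_thetas = tr$train_thetas,
           fitted_values = tr$fitted_values, sigma = tr$sigma,
           pve = tr$pve, lambda = tr$lambda)
    }))
  tryCatch(
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null"),
    error = function(e) stop("cannot write model file ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Deserialize a trained predictor from JSON
#'
#' Validates the schema version and the model invariants (sorted training
#' angles, positive sigma, at least two genes, grid spacing) before
#' reconstructing the predictor.
#'
#' @param path Model JSON written by [serialize_model()].
#' @return A `"trained_predictor"`.
#' @export
deserialize_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot parse model file: ",
                                               conditionMessage(e)))
  if (is.null(payload$schema_version))
    stop("model file has no schema_version field")
  if (!identical(as.character(payload$schema_version), MODEL_SCHEMA_VERSION))
    stop("unknown schema_version '", payload$schema_version,
         "' (supported: ", MODEL_SCHEMA_VERSION, ")")
  gl <- payload$genes
  # jsonlite may return either a data frame or a list of records
  records <- if (is.data.frame(gl)) {
    lapply(seq_len(nrow(gl)), function(i)
      list(gene_id = gl$gene_id[i],
           train_thetas = unlist(gl$train_thetas[i]),
           fitted_values = unlist(gl$fitted_values[i]),
           sigma = gl$sigma[i], pve = gl$pve[i], lambda = gl$lambda[i]))
  } else gl
  if (length(records) < 2) stop("validation error in field 'genes': ",
                                "need at least 2 genes")
  trends <- list()
  for (rec in records) {
    if (is.null(rec$sigma) || !is.finite(rec$sigma) || rec$sigma <= 0)
      stop("validation error in field 'sigma' for gene ", rec$gene_id,
           ": must be > 0")
    tt <- as.numeric(rec$train_thetas)
    if (is.unsorted(tt, strictly = TRUE))
      stop("validation error in field 'train_thetas' for gene ",
           rec$gene_id, ": must be strictly increasing")
    if (length(tt) != length(rec$fitted_values))
      stop("validation error in field 'fitted_values' for gene ",
           rec$gene_id, ": length mismatch with train_thetas")
    trends[[rec$gene_id]] <- structure(
      list(gene_id = rec$gene_id, train_thetas = tt,
           fitted_values = as.numeric(rec$fitted_values),
           sigma = rec$sigma, pve = rec$pve,
           lambda = if (is.null(rec$lambda)) NA_real_ else rec$lambda),
      class = "cyclic_trend")
  }
  K <- payload$grid$K
  if (is.null(K) || K < 2)
    stop("validation error in field 'grid.K': must be >= 2")
  structure(list(trends = trends, grid = phase_grid(K),
                 genes = names(trends),
                 manifest = payload$manifest,
                 normalization = payload$normalization),
            class = "trained_predictor")
}
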