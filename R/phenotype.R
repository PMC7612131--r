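#' Score questionnaire scale totals and clinical flags
#'
#' Flips reverse-scored items within each item's own response range, sums per
#' scale, and sets the standard clinical threshold flags: OCI-R total >= 21
#' and STAI total > 41 (strict). Missing responses are an error (no
#' imputation is performed).
#'
#' @param responses n x 209 response matrix/data.frame in manifest item
#'   order (columns named by item id).
#' @param manifest the \code{\link{item_manifest}}.
#' @return data.frame of class \code{scale_scores}: \code{subject}, one
#'   total column per scale, \code{ocir_ge_21}, \code{stai_gt_41}.
#' @export
score_scales <- function(responses, manifest = item_manifest()) {
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(manifest))
    stop(sprintf("expected %d item columns, got %d", nrow(manifest),
                 ncol(responses)))
  if (anyNA(responses)) {
    bad <- manifest$item_id[which(colSums(is.na(responses)) > 0)]
    stop("missing responses for item(s): ", paste(bad, collapse = ", "))
  }
  lo <- manifest$level_min
  hi <- manifest$level_min + manifest$n_levels - 1
  flipped <- responses
  rev <- which(manifest$reverse_scored)
  for (j in rev) flipped[, j] <- lo[j] + hi[j] - responses[, j]
  scales <- unique(manifest$scale)
  totals <- sapply(scales, function(s)
    rowSums(flipped[, manifest$scale == s, drop = FALSE]))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = 1,
                                             dimnames = list(NULL, scales))
  out <- data.frame(subject = seq_len(nrow(responses)), totals)
  out$ocir_ge_21 <- out$OCIR >= 21
  out$stai_gt_41 <- out$STAI > 41
  class(out) <- c("scale_scores", "data.frame")
  out
}

#' Dimension weight matrix
#'
#' A 209 x 3 item-weight matrix mapping raw item responses onto the
#' anxious-depression (AD), compulsivity (CIT) and social-withdrawal (SW)
#' dimensions. The canonical weights come from a large factor-analytic
#' reference study and are not redistributable here, so the packaged default
#' is SYNTHETIC: the generating loadings of a \code{\link{latent_model}},
#' clearly labelled non-canonical. A user-supplied CSV
#' (\code{item_id,w_AD,w_CIT,w_SW}, aligned to the manifest order) can be
#' loaded with \code{read_dimension_weights}.
#'
#' @param model a \code{\link{latent_model}}.
#' @return matrix of class \code{dimension_weights} with a
#'   \code{provenance} attribute.
#' @export
default_dimension_weights <- function(model = latent_model()) {
  w <- model$loadings
  attr(w, "provenance") <- "synthetic (generator loadings, non-canonical)"
  class(w) <- c("dimension_weights", class(w))
  w
}

#' @rdname default_dimension_weights
#' @param path CSV path.
#' @param manifest manifest used to check item alignment.
#' @export
read_dimension_weights <- function(path, manifest = item_manifest()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "w_AD", "w_CIT", "w_SW")
  if (!all(need %in% names(df))) stop("weights CSV needs columns ",
                                      paste(need, collapse = ", "))
  if (nrow(df) != nrow(manifest)) stop("weights must have 209 rows")
  if (!identical(df$item_id, manifest$item_id))
    stop("weights item order does not match the manifest")
  w <- as.matrix(df[, c("w_AD", "w_CIT", "w_SW")])
  dimnames(w) <- list(df$item_id, c("AD", "CIT", "SW"))
  attr(w, "provenance") <- paste0("file: ", path)
  class(w) <- c("dimension_weights", class(w))
  w
}

#' @rdname default_dimension_weights
#' @param weights a \code{dimension_weights} matrix.
#' @export
write_dimension_weights <- function(weights, path) {
  df <- data.frame(item_id = rownames(weights), w_AD = weights[, "AD"],
                   w_CIT = weights[, "CIT"], w_SW = weights[, "SW"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Project item responses onto the transdiagnostic dimensions
#'
#' Raw dimension score of factor f for a subject is the weighted sum
#' \eqn{\sum_i w_{if} x_i} over the 209 raw item responses; z-scored versions
#' (mean 0, SD 1 across the analysed cohort) are appended. The projection is
#' linear in the responses before z-scoring.
#'
#' @param responses n x 209 response matrix in manifest/weight item order.
#' @param weights a 209 x 3 \code{dimension_weights} matrix.
#' @param z also return z-scored columns (default TRUE; requires >= 2
#'   subjects with variance).
#' @return data.frame with \code{subject}, raw \code{AD}, \code{CIT},
#'   \code{SW} and (when \code{z}) \code{AD_z}, \code{CIT_z}, \code{SW_z}.
#' @export
project_dimensions <- function(responses, weights, z = TRUE) {
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(weights))
    stop(sprintf("responses have %d items but weights have %d rows",
                 ncol(responses), nrow(weights)))
  raw <- responses %*% unclass(weights)
  out <- data.frame(subject = seq_len(nrow(raw)), AD = raw[, "AD"],
                    CIT = raw[, "CIT"], SW = raw[, "SW"])
  if (z) {
    for (d in c("AD", "CIT", "SW"))
      out[[paste0(d, "_z")]] <- as.numeric(scale(out[[d]]))
  }
  out
}
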