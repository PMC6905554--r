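#' Write a fitted one-class model to a self-describing JSON file
#'
#' Serializes everything needed to reproduce decision scores exactly:
#' kernel specification, nu or C, the dual coefficients of the support
#' vectors, the offset (rho or R squared), the support vectors themselves,
#' the training dimension, and the package version.
#'
#' @param model A fitted [ocsvm()] or [svdd()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_occ_model()]
#' @export
write_occ_model <- function(model, path) {
  stopifnot(inherits(model, c("ocsvm", "svdd")))
  common <- list(
    model_class = class(model)[1],
    kernel = list(kind = model$kernel$kind, gamma = model$kernel$gamma),
    sv_alphas = model$alphas[model$sv_index],
    sv_index = model$sv_index,
    n_train = length(model$alphas),
    support_vectors = unname(model$support_vectors),
    d = model$d,
    package_version = as.character(utils::packageVersion("ocgene"))
  )
  extra <- if (inherits(model, "ocsvm")) {
    list(nu = model$nu, rho = model$rho)
  } else {
    list(C = model$C, radius_sq = model$radius_sq,
         center_norm_sq = model$center_norm_sq)
  }
  jsonlite::write_json(c(common, extra), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a serialized one-class model
#'
#' @param path File written by [write_occ_model()].
#' @return A model of class `ocsvm` or `svdd` whose decision scores match
#'   the original to machine precision.
#' @export
read_occ_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- matrix(as.numeric(j$support_vectors),
               nrow = length(j$sv_alphas), ncol = j$d)
  alphas <- numeric(j$n_train)
  alphas[j$sv_index] <- j$sv_alphas
  kernel <- kernel_spec(j$kernel$kind, gamma = j$kernel$gamma)
  if (j$model_class == "ocsvm") {
    structure(list(
      alphas = alphas, rho = j$rho, nu = j$nu, kernel = kernel,
      support_vectors = sv, sv_index = j$sv_index,
      slacks = NULL, objective = NULL, training_scores = NULL, d = j$d
    ), class = "ocsvm")
  } else {
    structure(list(
      alphas = alphas, radius_sq = j$radius_sq, C = j$C, kernel = kernel,
      support_vectors = sv, sv_index = j$sv_index, objective = NULL,
      center_norm_sq = j$center_norm_sq, d = j$d
    ), class = "svdd")
  }
}
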