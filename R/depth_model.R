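#' Fit the power-law depth-versus-offset model
#'
#' Fits `t = A * delta_s^phi` by nonlinear least squares in the original
#' (not log) intensity space, initialized from the ordinary log-log
#' regression. On noise-free power-law data both agree exactly.
#'
#' Units follow the phantom-table conventions: crossover offsets in mm,
#' depths in micrometres, so `A` carries units of um * mm^-phi.
#'
#' @param points data frame (or list of pairs) with columns `delta_s_co`
#'   (mm) and `t` (depth, um); at least 2 points, all coordinates > 0.
#' @param method `"nls"` (default, Levenberg-Marquardt) or `"loglog"`
#'   (log-log regression only).
#' @param optical_properties optional `(mu_a, mu_s_prime)` recorded with
#'   the model.
#' @return A `depth_model`: list with `A`, `phi`, `optical_properties`,
#'   `fit_points`, `residual_norm`.
#' @export
fit_power_law <- function(points, method = c("nls", "loglog"),
                          optical_properties = c(NA_real_, NA_real_)) {
  method <- match.arg(method)
  points <- as.data.frame(points)
  if (!all(c("delta_s_co", "t") %in% names(points))) {
    names(points)[1:2] <- c("delta_s_co", "t")
  }
  x <- as.numeric(points$delta_s_co); y <- as.numeric(points$t)
  if (length(x) < 2) stop("need at least 2 points to fit")
  if (any(x <= 0) || any(y <= 0)) stop("all coordinates must be > 0")
  if (max(x) - min(x) <= 0) stop("singular fit: all offsets equal")
  ll <- lm(log(y) ~ log(x))
  A0 <- exp(coef(ll)[[1]]); phi0 <- coef(ll)[[2]]
  if (method == "nls") {
    fit <- minpack.lm::nlsLM(y ~ A * x^phi,
                             start = list(A = A0, phi = phi0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    A <- coef(fit)[["A"]]; phi <- coef(fit)[["phi"]]
    rn <- sqrt(sum(stats::residuals(fit)^2))
  } else {
    A <- A0; phi <- phi0
    rn <- sqrt(sum((y - A * x^phi)^2))
  }
  structure(list(A = A, phi = phi,
                 optical_properties = optical_properties,
                 fit_points = data.frame(delta_s_co = x, t = y),
                 residual_norm = rn,
                 units = c(delta_s = "mm", t = "um")),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("<depth_model> t* = %.4g * delta_s^%.4g  (t in %s, offset in %s)\n",
              x$A, x$phi, x$units[["t"]], x$units[["delta_s"]]))
  cat(sprintf("  %d fit points, residual norm %.4g\n",
              nrow(x$fit_points), x$residual_norm))
  invisible(x)
}

#' Predict sampling depth from spatial offset
#'
#' @param model a `depth_model`.
#' @param delta_s spatial offset(s), mm, > 0.
#' @return Predicted depth `A * delta_s^phi` (um).
#' @export
predict_depth <- function(model, delta_s) {
  stopifnot(inherits(model, "depth_model"))
  if (any(delta_s <= 0)) stop("delta_s must be > 0")
  model$A * delta_s^model$phi
}

#' Spatial offset required to probe a target depth
#'
#' Inverse of [predict_depth()]: `(target_depth / A)^(1 / phi)`.
#'
#' @param model a `depth_model`.
#' @param target_depth desired depth(s), um, > 0.
#' @return Required spatial offset, mm.
#' @export
required_offset <- function(model, target_depth) {
  stopifnot(inherits(model, "depth_model"))
  if (any(target_depth <= 0)) stop("target_depth must be > 0")
  (target_depth / model$A)^(1 / model$phi)
}

#' Fit one depth model per optical-property group
#'
#' Groups phantoms by identical `(mu_a, mu_s_prime)`, keeps entries whose
#' crossover was found, and fits [fit_power_law()] per group with at least
#' 2 usable points. Groups with fewer usable points are reported as
#' unfittable rather than forced through a fit (with strongly scattering
#' top layers the crossover loses its physical meaning).
#'
#' @param per_phantom list of `list(phantom = phantom_spec, thickness_um =
#'   depth, crossover = crossover_result)` entries, or a data frame with
#'   columns `recipe`, `mu_a`, `mu_s_prime`, `thickness_um`,
#'   `delta_s_co`, `status`.
#' @return List with `models` (named list of `depth_model`) and
#'   `unfittable` (named list with the usable point count per skipped
#'   group).
#' @export
build_depth_curves <- function(per_phantom) {
  if (length(per_phantom) == 0) stop("empty input")
  if (!is.data.frame(per_phantom)) {
    per_phantom <- do.call(rbind, lapply(per_phantom, function(e) {
      data.frame(recipe = e$phantom$recipe_name,
                 mu_a = e$phantom$mu_a,
                 mu_s_prime = e$phantom$mu_s_prime,
                 thickness_um = e$thickness_um,
                 delta_s_co = e$crossover$delta_s_co,
                 status = e$crossover$status)
    }))
  }
  groups <- split(per_phantom,
                  interaction(per_phantom$recipe, per_phantom$mu_a,
                              per_phantom$mu_s_prime, drop = TRUE))
  models <- list()
  unfittable <- list()
  for (g in groups) {
    key <- as.character(g$recipe[1])
    usable <- g[g$status == "crossover_found" & is.finite(g$delta_s_co) &
                  g$delta_s_co > 0 & g$thickness_um > 0, , drop = FALSE]
    if (nrow(usable) < 2 ||
        max(usable$delta_s_co) - min(usable$delta_s_co) <= 0) {
      unfittable[[key]] <- nrow(usable)
      next
    }
    models[[key]] <- fit_power_law(
      data.frame(delta_s_co = usable$delta_s_co, t = usable$thickness_um),
      optical_properties = c(g$mu_a[1], g$mu_s_prime[1]))
  }
  list(models = models, unfittable = unfittable)
}

#' Serialize depth models
#'
#' Writes a JSON file per fitted model plus a CSV table of recipe, optical
#' properties and fitted parameters.
#'
#' @param curves result of [build_depth_curves()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the CSV path.
#' @export
write_depth_curves <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(curves$models), function(nm) {
    m <- curves$models[[nm]]
    jsonlite::write_json(list(recipe = nm, A = m$A, phi = m$phi,
                              units = as.list(m$units),
                              optical_properties = m$optical_properties,
                              fit_points = m$fit_points,
                              residual_norm = m$residual_norm),
                         file.path(dir, paste0("depth_model_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    data.frame(recipe = nm, mu_a = m$optical_properties[1],
               mu_s_prime = m$optical_properties[2], A = m$A, phi = m$phi,
               residual_norm = m$residual_norm)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recipe = character(), mu_a = numeric(),
               mu_s_prime = numeric(), A = numeric(), phi = numeric(),
               residual_norm = numeric())
  path <- file.path(dir, "depth_models.csv")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
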