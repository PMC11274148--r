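#' Mesh-sensitivity study container
#'
#' Mean and maximum wall shear stress from steady solves on a sequence of
#' grids of strictly increasing element count; the finest grid is the
#' reference.
#'
#' @param n_elements element counts, strictly increasing, length >= 2.
#' @param mean_wss,max_wss WSS summaries per mesh (Pa).
#' @return data.frame of class \code{mesh_study}.
#' @export
mesh_study <- function(n_elements, mean_wss, max_wss) {
  if (length(n_elements) < 2) stop("need at least 2 meshes")
  if (any(diff(n_elements) <= 0)) stop("element counts must be strictly increasing")
  stopifnot(length(mean_wss) == length(n_elements),
            length(max_wss) == length(n_elements))
  d <- data.frame(n_elements = n_elements, mean_wss_pa = mean_wss,
                  max_wss_pa = max_wss)
  class(d) <- c("mesh_study", "data.frame")
  d
}

#' Relative percentage difference against the finest mesh
#'
#' For each mesh, \eqn{100\,|x_i - x_{finest}| / |x_{finest}|} for the mean
#' and maximum WSS; the finest entry is 0 by construction.
#'
#' @param study a \code{\link{mesh_study}}.
#' @return data.frame: n_elements, rpd_mean, rpd_max (percent).
#' @export
sensitivity_curve <- function(study) {
  stopifnot(inherits(study, "mesh_study"))
  n <- nrow(study)
  ref_mean <- study$mean_wss_pa[n]
  ref_max <- study$max_wss_pa[n]
  if (ref_mean == 0 || ref_max == 0) {
    stop("finest-mesh reference value is zero; relative difference undefined")
  }
  data.frame(n_elements = study$n_elements,
             rpd_mean = 100 * abs(study$mean_wss_pa - ref_mean) / abs(ref_mean),
             rpd_max = 100 * abs(study$max_wss_pa - ref_max) / abs(ref_max))
}

#' Select the coarsest acceptable mesh
#'
#' Smallest element count whose mean AND max WSS both lie within
#' \code{tolerance} percent of the finest mesh. If none qualifies (only
#' possible for tolerance below 0, since the finest mesh has 0 difference),
#' the finest mesh is returned with a warning.
#'
#' @param study a \code{\link{mesh_study}}.
#' @param tolerance relative-percentage-difference tolerance (percent).
#' @return selected element count.
#' @export
select_mesh <- function(study, tolerance = 2) {
  sc <- sensitivity_curve(study)
  ok <- which(sc$rpd_mean <= tolerance & sc$rpd_max <= tolerance)
  if (length(ok) == 0) {
    warning("no mesh within tolerance; returning the finest")
    return(study$n_elements[nrow(study)])
  }
  study$n_elements[min(ok)]
}

#' CFL-based time-step selection
#'
#' \eqn{\Delta t = C\,h/u} for minimum edge length h, maximum velocity u and
#' Courant number C. Also reports whether the step falls within the
#' 0.0005-0.002 s band typical of patient-specific transient aortic solves.
#'
#' @param min_edge minimum mesh edge length (m).
#' @param max_velocity maximum velocity magnitude (m/s), > 0.
#' @param courant Courant number (default 1).
#' @param band reference band of acceptable steps (s).
#' @return list: \code{dt} (s), \code{in_band} (logical), \code{band}.
#' @export
cfl_timestep <- function(min_edge, max_velocity, courant = 1,
                         band = c(5e-4, 2e-3)) {
  if (max_velocity <= 0) stop("max_velocity must be > 0")
  if (min_edge <= 0 || courant <= 0) stop("min_edge and courant must be > 0")
  dt <- courant * min_edge / max_velocity
  list(dt = dt, in_band = dt >= band[1] & dt <= band[2], band = band)
}

#' Read a mesh-sensitivity study CSV (n_elements, mean_wss_pa, max_wss_pa)
#' @param path CSV path.
#' @return a \code{mesh_study}.
#' @export
read_mesh_study_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("n_elements", "mean_wss_pa", "max_wss_pa")
  if (!all(need %in% names(d))) {
    stop("mesh study CSV must have columns ", paste(need, collapse = ", "))
  }
  mesh_study(d$n_elements, d$mean_wss_pa, d$max_wss_pa)
}
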