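# Synthetic study builder: a labeled grid of media x charges x sizes, each
# cell a mixture of motion models, standing in for tracking experiments of
# fluorescent polystyrene tracers in native and artificial colonic mucus.

.STUDY_MEDIA <- c("PNCM", "PACM-HEC", "PACM-PAA")
.STUDY_CHARGES <- c("positive", "negative")
.STUDY_SIZES <- c(100, 200, 1000)

#' Build a synthetic study design
#'
#' Returns the full media x charges x sizes grid with a per-cell mixture of
#' motion models. Three presets are provided:
#'
#' * `"heterogeneous"` (default): the emulated study conditions. Each cell
#'   mixes immobile, subdiffusive (fractional Brownian, H < 0.5) and freely
#'   diffusing populations; media differ in mixture weights and mobility
#'   scales, positive charge shifts weight toward the immobile component
#'   and halves diffusivities (electrostatic binding to the mucin network),
#'   and diffusivities scale inversely with particle size.
#' * `"disjoint"`: one Brownian population per medium with diffusivities
#'   0.001 / 0.1 / 10 um^2/s -- non-overlapping feature supports, an easy
#'   classification control.
#' * `"identical"`: every medium uses the PNCM mixture -- chance-level
#'   classification control.
#'
#' @param n_per_cell Trajectories per (medium, charge, size) cell.
#' @param design Preset name.
#' @param media,charges,sizes Grid levels (defaults: the canonical study
#'   grid).
#' @param n_frames,dt,loc_noise_sigma Acquisition parameters shared by all
#'   cells (defaults: 100 frames, 1 s, 0.03 um localization noise).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_per_cell = 50L,
                         design = c("heterogeneous", "disjoint", "identical"),
                         media = .STUDY_MEDIA, charges = .STUDY_CHARGES,
                         sizes = .STUDY_SIZES,
                         n_frames = 100L, dt = 1, loc_noise_sigma = 0.03) {
  design <- match.arg(design)
  cells <- list()
  for (medium in media) for (charge in charges) for (size in sizes) {
    mix <- .cell_mixture(design, medium, charge, size)
    cells[[length(cells) + 1L]] <- list(medium = medium, charge = charge,
                                        size_nm = size, n = as.integer(n_per_cell),
                                        mixture = mix)
  }
  .validate_design(structure(list(cells = cells, n_frames = as.integer(n_frames),
                                  dt = dt, loc_noise_sigma = loc_noise_sigma,
                                  name = design),
                             class = "study_design"))
}

.validate_design <- function(design) {
  for (cell in design$cells) {
    w <- vapply(cell$mixture, function(m) m$weight, numeric(1L))
    if (abs(sum(w) - 1) > 1e-8) {
      stop("mixture weights in cell (", cell$medium, ", ", cell$charge, ", ",
           cell$size_nm, " nm) sum to ", sum(w), ", not 1")
    }
    if (any(w < 0)) stop("mixture weights must be nonnegative")
  }
  design
}

# mobility scale vs particle size: D ~ 1/a (Stokes-Einstein), anchored at
# 0.8 um^2/s free diffusion for 100 nm tracers in the interstitial fluid
.size_D <- function(size_nm) 0.8 * 100 / size_nm

.cell_mixture <- function(design, medium, charge, size) {
  D_free <- .size_D(size)
  if (design == "disjoint") {
    D <- c("PNCM" = 0.001, "PACM-HEC" = 0.1, "PACM-PAA" = 10)[[medium]]
    return(list(list(model = "brownian", weight = 1, D = D)))
  }
  if (design == "identical") medium <- "PNCM"
  par <- switch(medium,
    "PNCM"     = list(w = c(0.35, 0.40, 0.25), Dmul = 1.0, H = 0.25),
    "PACM-HEC" = list(w = c(0.40, 0.40, 0.20), Dmul = 0.7, H = 0.30),
    "PACM-PAA" = list(w = c(0.55, 0.35, 0.10), Dmul = 0.4, H = 0.20))
  w <- par$w
  Dmul <- par$Dmul
  if (charge == "positive") {
    w <- c(w[1] + 0.30, w[2], w[3] * 0.5)
    w <- w / sum(w)
    Dmul <- Dmul * 0.5
  }
  list(
    list(model = "immobile", weight = w[1]),
    list(model = "fbm", weight = w[2], D = 0.1 * D_free * Dmul, hurst_H = par$H),
    list(model = "brownian", weight = w[3], D = D_free * Dmul)
  )
}

#' @export
print.study_design <- function(x, ...) {
  n_tot <- sum(vapply(x$cells, function(c) c$n, integer(1L)))
  cat(sprintf("<study_design> '%s': %d cells, %d trajectories, %d frames @ dt = %g s, noise sd = %g um\n",
              x$name, length(x$cells), n_tot, x$n_frames, x$dt, x$loc_noise_sigma))
  invisible(x)
}

#' Read a study design from a YAML config file
#'
#' The file holds top-level `n_frames`, `dt`, `loc_noise_sigma` and a
#' `cells` sequence; each cell has `medium`, `charge`, `size_nm`,
#' `n_trajectories` (the bare key `n` is a YAML 1.1 boolean and must be
#' quoted, so the long name is preferred) and a `mixture` sequence of
#' components with `model`, `weight` and model parameters (`D`, `hurst_H`,
#' `confinement_radius`, `drift_v`).
#'
#' @param path YAML file path.
#' @return A `study_design`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cells)) stop("config must define a 'cells' sequence")
  cells <- lapply(cfg$cells, function(cell) {
    n <- cell$n_trajectories %||% cell[["n"]]
    if (is.null(n)) stop("each cell needs n_trajectories")
    list(medium = cell$medium, charge = cell$charge,
         size_nm = as.numeric(cell$size_nm), n = as.integer(n),
         mixture = lapply(cell$mixture, function(m) m))
  })
  .validate_design(structure(
    list(cells = cells,
         n_frames = as.integer(cfg$n_frames %||% 100L),
         dt = as.numeric(cfg$dt %||% 1),
         loc_noise_sigma = as.numeric(cfg$loc_noise_sigma %||% 0.03),
         name = cfg$name %||% basename(path)),
    class = "study_design"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full labeled study
#'
#' Simulates every cell of a [study_design()]. Component counts within a
#' cell are apportioned deterministically from the mixture weights
#' (largest-remainder rounding), so cell totals match the design exactly.
#'
#' @param design A [study_design()].
#' @param seed Integer seed (bit-reproducible output).
#' @param temperature_T Temperature in kelvin for the particle contexts.
#' @return An object of class `synthetic_study`: list with `trajectories`
#'   (named list of [trajectory()]), `labels` (data frame: particle,
#'   medium, charge, nominal_diameter, model), `contexts` (named list of
#'   [particle_context()]), `design`.
#' @export
build_synthetic_study <- function(design = study_design(), seed = 1L,
                                  temperature_T = 310.15) {
  stopifnot(inherits(design, "study_design"))
  .validate_design(design)
  trajs <- list()
  labels <- list()
  cell_i <- 0L
  for (cell in design$cells) {
    cell_i <- cell_i + 1L
    w <- vapply(cell$mixture, function(m) m$weight, numeric(1L))
    counts <- .apportion(cell$n, w)
    for (j in seq_along(cell$mixture)) {
      if (counts[j] == 0L) next
      comp <- cell$mixture[[j]]
      cfg <- sim_config(model = comp$model, n_trajectories = counts[j],
                        n_frames = design$n_frames, dt = design$dt,
                        D = comp$D %||% 0.1,
                        hurst_H = comp$hurst_H %||% 0.5,
                        confinement_radius = comp$confinement_radius %||% 0.5,
                        drift_v = comp$drift_v %||% 0.1,
                        states = comp$states %||% list(D = c(0.01, 1),
                                                       P = matrix(c(0.95, 0.05, 0.05, 0.95),
                                                                  2, 2, byrow = TRUE)),
                        loc_noise_sigma = design$loc_noise_sigma)
      prefix <- sprintf("c%02d_%s", cell_i, comp$model)
      sims <- simulate_trajectories(cfg, seed = .sub_seed(seed, cell_i * 100L + j),
                                    id_prefix = prefix)
      for (tr in sims) {
        trajs[[tr$particle_id]] <- tr
        labels[[length(labels) + 1L]] <- data.frame(
          particle = tr$particle_id, medium = cell$medium, charge = cell$charge,
          nominal_diameter = cell$size_nm, model = comp$model,
          stringsAsFactors = FALSE)
      }
    }
  }
  labels <- do.call(rbind, labels)
  contexts <- lapply(seq_len(nrow(labels)), function(i) {
    particle_context(radius_a = labels$nominal_diameter[i] / 2 * 1e-9,
                     charge = labels$charge[i],
                     nominal_diameter = labels$nominal_diameter[i],
                     medium = labels$medium[i],
                     temperature_T = temperature_T, dimensionality_d = 2L)
  })
  names(contexts) <- labels$particle
  structure(list(trajectories = trajs, labels = labels, contexts = contexts,
                 design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d trajectories\n", length(x$trajectories)))
  print(table(x$labels$medium, x$labels$charge))
  invisible(x)
}

# largest-remainder apportionment of n into parts proportional to w
.apportion <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1L
  }
  as.integer(counts)
}

#' Write study labels to CSV
#'
#' @param study A [build_synthetic_study()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_labels <- function(study, path) {
  utils::write.csv(study$labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
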