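# ---- simulation & rendering parameter objects ------------------------------

#' Simulation parameters for the gametophyte growth model
#'
#' One simulation step is one 48-h imaging window. During the apical-initial
#' phase the single apical cell either self-renews by an oblique division
#' (probability `p_oblique`) or terminates by a periclinal division
#' (`p_terminate`), after which the tissue switches to the multicellular
#' apical meristem phase: every marginal cell behaves as a packet upper cell
#' (anticlinal Type I with probability `q1`, periclinal Type II with `q2`) and
#' every submarginal cell as a packet lower cell (Type III `q3`, Type IV
#' `q4`). Inner cells are ordinary and do not divide. Non-dividing cells
#' expand by the linear factor `growth_factor` per window; any cell smaller
#' than `size_gate` may not divide.
#'
#' Default probabilities are configuration placeholders reproducing the
#' qualitative ordering reported for this tissue (periclinal > anticlinal in
#' the marginal layer packets, anticlinal > periclinal in the submarginal
#' ones); they are not literature estimates.
#'
#' @param n_windows number of 48-h windows to simulate
#' @param p_oblique per-window probability that the apical initial self-renews
#'   by an oblique division
#' @param p_terminate per-window probability that the apical initial divides
#'   periclinally and terminates
#' @param q1,q2 per-window probabilities of anticlinal (Type I) and periclinal
#'   (Type II) division of an upper (marginal) packet cell
#' @param q3,q4 per-window probabilities of anticlinal (Type III) and
#'   periclinal (Type IV) division of a lower (submarginal) packet cell
#' @param meristem_fraction fraction of the margin arc, centred on the apex
#'   (the +y-most margin point), whose marginal cells behave as packet upper
#'   cells; marginal cells outside the sector are ordinary and do not divide.
#'   Division activity in the real tissue is restricted to the apical
#'   meristem domain, so only part of the margin proliferates.
#' @param p_trichome per-window trichome initiation probability per eligible
#'   (marginal or inner, non-trichome) cell
#' @param growth_factor per-window linear expansion factor for non-dividing
#'   cells (>= 1)
#' @param size_gate minimum cell area (um^2) required to divide
#' @param rng_seed integer seed; simulations are reproducible bit for bit
#' @param p_derivative per-window anticlinal division probability of the
#'   apical initial's immediate derivatives (the phase-A on-ramp that widens
#'   the marginal row)
#' @param init_rows,init_cols starting tissue: 1 x 1 gives the spore; larger
#'   values start at the established-meristem stage as a grid of
#'   `cell_w` x `cell_h` um rectangles (the top row facing the margin)
#' @param cell_w,cell_h initial rectangle size (um) for grid starts
#' @param spore_size side (um) of the square spore cell
#' @param trichome_elong outward elongation (um/window) of the trichome apex
#' @param max_cells viability limit; exceeding it aborts the simulation
#' @return a `sim_params` list, validated
#' @export
sim_params <- function(n_windows = 6, p_oblique = 0.8, p_terminate = 0.2,
                       q1 = 0.15, q2 = 0.35, q3 = 0.30, q4 = 0.10,
                       meristem_fraction = 0.4,
                       p_trichome = 0.02, growth_factor = 1.15,
                       size_gate = 100, rng_seed = 1, p_derivative = 0.5,
                       init_rows = 1, init_cols = 1, cell_w = 18,
                       cell_h = 14, spore_size = 30, trichome_elong = 10,
                       max_cells = 5000) {
  p <- list(n_windows = as.integer(n_windows), p_oblique = p_oblique,
            p_terminate = p_terminate, q1 = q1, q2 = q2, q3 = q3, q4 = q4,
            meristem_fraction = meristem_fraction,
            p_trichome = p_trichome, growth_factor = growth_factor,
            size_gate = size_gate, rng_seed = as.integer(rng_seed),
            p_derivative = p_derivative, init_rows = as.integer(init_rows),
            init_cols = as.integer(init_cols), cell_w = cell_w,
            cell_h = cell_h, spore_size = spore_size,
            trichome_elong = trichome_elong, max_cells = as.integer(max_cells))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  probs <- c("p_oblique", "p_terminate", "q1", "q2", "q3", "q4", "p_trichome",
             "p_derivative")
  for (nm in probs)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be a probability in [0, 1]")
  if (p$q1 + p$q2 > 1) stop("q1 + q2 must not exceed 1")
  if (p$q3 + p$q4 > 1) stop("q3 + q4 must not exceed 1")
  if (p$p_oblique + p$p_terminate > 1)
    stop("p_oblique + p_terminate must not exceed 1")
  if (p$growth_factor < 1) stop("growth_factor must be >= 1")
  if (p$meristem_fraction <= 0 || p$meristem_fraction > 1)
    stop("meristem_fraction must be in (0, 1]")
  if (p$n_windows < 0) stop("n_windows must be >= 0")
  if (p$size_gate < 0) stop("size_gate must be >= 0")
  invisible(p)
}

#' Rendering parameters for synthetic membrane-stain images
#'
#' Emulates the appearance of a propidium-iodide wall stain: bright cell
#' outlines over a dim cytoplasm and a dark background, blurred by the optics
#' and corrupted by additive detector noise. Intensities are arbitrary units
#' on a 16-bit-like scale.
#'
#' @param pixel_size um per pixel (> 0)
#' @param wall_intensity,interior_intensity,background_intensity mean signal
#'   of wall pixels, cell interiors, and background; must satisfy
#'   wall > interior >= background
#' @param blur_sigma Gaussian blur standard deviation (pixels)
#' @param noise_sd additive Gaussian noise standard deviation
#' @param rng_seed integer seed for the noise
#' @return a `render_params` list
#' @export
render_params <- function(pixel_size = 0.7, wall_intensity = 3000,
                          interior_intensity = 300, background_intensity = 50,
                          blur_sigma = 1, noise_sd = 60, rng_seed = 1) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!(wall_intensity > interior_intensity &&
        interior_intensity >= background_intensity))
    stop("require wall_intensity > interior_intensity >= background_intensity")
  if (blur_sigma < 0 || noise_sd < 0)
    stop("blur_sigma and noise_sd must be >= 0")
  rp <- list(pixel_size = pixel_size, wall_intensity = wall_intensity,
             interior_intensity = interior_intensity,
             background_intensity = background_intensity,
             blur_sigma = blur_sigma, noise_sd = noise_sd,
             rng_seed = as.integer(rng_seed))
  class(rp) <- "render_params"
  rp
}
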