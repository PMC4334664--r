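# Four-population canonical microcircuit: populations, signed connectivity,
# convolution dynamics and firing-rate nonlinearity.

# Signed intrinsic weight matrix (target row, source column) in table units.
# G1 SS->SS, G2 SPC->SS, G3 II->SS, G4 II->II, G5 SS->II, G6 DPC->II,
# G7 SPC->SPC, G8 SS->SPC, G9 II->DPC, G10 DPC->DPC.
# Inhibitory: G1 G2 G3 G4 G7 G9 G10; excitatory: G5 G6 G8.
intrinsic_matrix <- function(g) {
  stopifnot(length(g) == 10, all(g >= 0))
  W <- matrix(0, 4, 4, dimnames = list(CMC_POPULATIONS, CMC_POPULATIONS))
  W["SS",  "SS"]  <- -g[1]
  W["SS",  "SPC"] <- -g[2]
  W["SS",  "II"]  <- -g[3]
  W["II",  "II"]  <- -g[4]
  W["II",  "SS"]  <- +g[5]
  W["II",  "DPC"] <- +g[6]
  W["SPC", "SPC"] <- -g[7]
  W["SPC", "SS"]  <- +g[8]
  W["DPC", "II"]  <- -g[9]
  W["DPC", "DPC"] <- -g[10]
  W
}

#' Build the two-source connectivity graph
#'
#' Assembles the signed, weighted directed graph over the eight populations
#' of a two-source network (sources labeled lower/higher). Forward extrinsic
#' connections originate in the superficial pyramidal cells of the lower
#' source and terminate (excitatory) on the spiny stellate cells of the
#' higher source; backward connections originate in the deep pyramidal cells
#' of the higher source and terminate (inhibitory) on the superficial
#' pyramidal cells and inhibitory interneurons of the lower source.
#' `direction = "reversed"` swaps which source sends the forward versus
#' backward projections, leaving all intrinsic structure untouched; applying
#' it twice restores the original graph.
#'
#' @param theta named vector of log-scaling deviations (default: prior means)
#' @param direction `"veridical"` or `"reversed"`
#' @param priors a [cmc_priors()] object
#' @return an object of class `cmc_network`: list with 8x8 matrices
#'   `intrinsic` and `extrinsic` (signed weights in table units), the
#'   population labels, and the direction
#' @export
#' @examples
#' net <- build_network()
#' net$intrinsic[1:4, 1:4]  # Table values with fixed signs
build_network <- function(theta = NULL, direction = c("veridical", "reversed"),
                          priors = cmc_priors()) {
  direction <- match.arg(direction)
  phys <- theta_to_phys(if (is.null(theta)) cmc_theta(priors) else theta, priors)
  labs <- paste(rep(CMC_POPULATIONS, 2), rep(1:2, each = 4), sep = "_")
  Wint <- matrix(0, 8, 8, dimnames = list(labs, labs))
  for (s in 1:2) {
    idx <- (s - 1) * 4 + 1:4
    Wint[idx, idx] <- intrinsic_matrix(phys[paste0("G", 1:10, "_", s)])
  }
  Wext <- matrix(0, 8, 8, dimnames = list(labs, labs))
  lo <- if (direction == "veridical") 1 else 2  # source sending forward
  hi <- 3 - lo
  i <- function(pop, s) (s - 1) * 4 + match(pop, CMC_POPULATIONS)
  if (lo == hi) stop("self-extrinsic coupling requested")
  Wext[i("SS", hi), i("SPC", lo)] <- +phys["a_fwd"]
  Wext[i("SPC", lo), i("DPC", hi)] <- -phys["a_bwd_spc"]
  Wext[i("II", lo), i("DPC", hi)] <- -phys["a_bwd_ii"]
  structure(list(intrinsic = Wint, extrinsic = Wext,
                 populations = labs, direction = direction,
                 forward_source = lo, backward_source = hi),
            class = "cmc_network")
}

#' Sigmoid firing-rate function
#'
#' Centered logistic transformation of population depolarization to mean
#' firing rate: `S(v) = 1 / (1 + exp(-slope * v)) - 1/2`. Monotone, bounded
#' in (-1/2, 1/2), antisymmetric about zero with `S(0) = 0`, and with
#' derivative `slope / 4` at the origin, so the origin is a fixed point of
#' the network dynamics and the linearized synaptic gain is `slope / 4`.
#'
#' @param v depolarization (any numeric)
#' @param slope sigmoid slope parameter (default prior mean 2/3)
#' @return firing rate, dimensionless
#' @export
sigmoid_rate <- function(v, slope = 2/3) {
  stopifnot(all(is.finite(v)))
  1 / (1 + exp(-slope * v)) - 0.5
}

#' Time derivative of the neuronal states
#'
#' Implements the synaptic convolution dynamics of the two-source network.
#' Each population has a depolarization `v` and its derivative; with rate
#' constant `kappa = 1/T` the second-order dynamics are
#' `vddot = kappa * u - 2 * kappa * vdot - kappa^2 * v`, where `u` is the
#' signed, weighted sum of presynaptic firing rates plus the exogenous drive
#' for the spiny stellate populations. The impulse response of an isolated
#' population is the alpha kernel `kappa^2 * t * exp(-kappa * t)`, peaking
#' at `t = T`. Extrinsic connections are treated as instantaneous here (the
#' conduction delay is applied spectrally as a phase factor); this is the
#' delay-free vector field whose Jacobian at the origin underlies the
#' transfer functions.
#'
#' @param state numeric vector of length 16: the eight depolarizations
#'   (source-major, populations in order SS, SPC, II, DPC) followed by their
#'   derivatives
#' @param theta named log-deviation vector (default prior means)
#' @param input exogenous drive per source (length 2), entering the spiny
#'   stellate populations only
#' @param direction hierarchy direction, see [build_network()]
#' @param priors,config model priors and configuration
#' @return numeric vector of length 16, the state time-derivative
#' @export
state_derivatives <- function(state, theta = NULL, input = c(0, 0),
                              direction = "veridical",
                              priors = cmc_priors(), config = cmc_config()) {
  stopifnot(length(state) == 16, length(input) == 2)
  phys <- theta_to_phys(if (is.null(theta)) cmc_theta(priors) else theta, priors)
  tc <- phys[paste0("T", rep(1:4, 2), "_", rep(1:2, each = 4))] / 1000
  if (any(tc <= 0)) stop("nonpositive time constant")
  kappa <- 1 / tc
  net <- build_network(theta, direction, priors)
  W <- (net$intrinsic + net$extrinsic) * config$coupling_scale
  v <- state[1:8]
  vd <- state[9:16]
  u <- drop(W %*% sigmoid_rate(v, phys["slope"]))
  ss_idx <- c(1, 5)
  u[ss_idx] <- u[ss_idx] + config$drive_scale * input
  unname(c(vd, kappa * u - 2 * kappa * vd - kappa^2 * v))
}
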