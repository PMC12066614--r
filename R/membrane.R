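#' Passive membrane properties
#'
#' Uniform passive constants for all compartments. The membrane time
#' constant is derived, `tau_m = Rm * Cm` (kOhm cm^2 x uF/cm^2 = ms), and
#' must equal any explicitly supplied value to within 1e-9.
#'
#' @param rm_kohm_cm2 Specific membrane resistance (kOhm cm^2), default 28.
#' @param ra_ohm_cm Axial resistivity (Ohm cm), default 150.
#' @param cm_uf_cm2 Specific membrane capacitance (uF/cm^2), default 1.
#' @param vrest_mv Resting potential (mV), default -65.
#' @param tau_m_ms Optional membrane time constant (ms) used only as a
#'   consistency check.
#' @return An object of class `passive_properties`.
#' @export
passive_properties <- function(rm_kohm_cm2 = 28, ra_ohm_cm = 150,
                               cm_uf_cm2 = 1.0, vrest_mv = -65,
                               tau_m_ms = NULL) {
  stopifnot(rm_kohm_cm2 > 0, ra_ohm_cm > 0, cm_uf_cm2 > 0)
  tau <- rm_kohm_cm2 * cm_uf_cm2
  if (!is.null(tau_m_ms) && abs(tau - tau_m_ms) > 1e-9) {
    stop(sprintf(
      "inconsistent membrane constants: Rm * Cm = %g ms but tau_m_ms = %g ms",
      tau, tau_m_ms), call. = FALSE)
  }
  structure(
    list(rm_kohm_cm2 = rm_kohm_cm2, ra_ohm_cm = ra_ohm_cm,
         cm_uf_cm2 = cm_uf_cm2, vrest_mv = vrest_mv, tau_m_ms = tau),
    class = "passive_properties"
  )
}

GATE_KEYS <- c("name", "exponent", "inf_vhalf_mv", "inf_k_mv", "tau_min_ms",
               "tau_amp_ms", "tau_vhalf_mv", "tau_ka_mv", "tau_kb_mv")

#' Voltage-gated channel model
#'
#' Hodgkin-Huxley style channel: current density
#' `i = gbar * prod(gate^exponent) * (V - Erev)` (mA/cm^2 with gbar in
#' S/cm^2 and V in mV). Each gate relaxes first-order toward a Boltzmann
#' steady state `x_inf(V) = 1 / (1 + exp(-(V - vhalf) / k))` (k < 0 for
#' inactivation gates) with a bell-shaped voltage-dependent time constant
#' `tau(V) = tau_min + tau_amp / (exp((V - tau_vhalf) / ka) +
#' exp(-(V - tau_vhalf) / kb))`.
#'
#' @param name Channel name.
#' @param erev_mv Reversal potential (mV).
#' @param gbar_s_cm2 Named numeric vector of maximal conductance densities
#'   (S/cm^2) per compartment kind; kinds absent from the map get 0.
#' @param gates List of gate parameter lists with keys `name`, `exponent`,
#'   `inf_vhalf_mv`, `inf_k_mv`, `tau_min_ms`, `tau_amp_ms`, `tau_vhalf_mv`,
#'   `tau_ka_mv`, `tau_kb_mv`.
#' @param gbar_slope_per_um Optional named numeric vector: linear-in-distance
#'   density rule, `g(d) = gbar * max(0, 1 + slope * d)` with `d` the path
#'   distance from the root (um). Default uniform (no slope).
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(name, erev_mv, gbar_s_cm2, gates,
                          gbar_slope_per_um = NULL) {
  stopifnot(is.character(name), length(gates) >= 1)
  if (is.null(names(gbar_s_cm2)) || any(!nzchar(names(gbar_s_cm2)))) {
    stop("`gbar_s_cm2` must be a named vector (compartment kind -> S/cm^2)",
         call. = FALSE)
  }
  if (any(gbar_s_cm2 < 0)) stop("conductance densities must be >= 0",
                                call. = FALSE)
  gates <- lapply(gates, function(g) {
    missing <- setdiff(GATE_KEYS, names(g))
    if (length(missing) > 0) {
      stop(sprintf("gate spec for channel '%s' is missing key(s): %s",
                   name, paste(missing, collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(names(g), GATE_KEYS)
    if (length(extra) > 0) {
      stop(sprintf("gate spec for channel '%s' has unknown key(s): %s",
                   name, paste(extra, collapse = ", ")), call. = FALSE)
    }
    if (!is.character(g$name)) {
      stop(sprintf("gate name in channel '%s' must be a string (quote it in YAML if it reads as a boolean)",
                   name), call. = FALSE)
    }
    if (g$tau_min_ms <= 0 || g$tau_amp_ms < 0) {
      stop("gate time constants must be positive", call. = FALSE)
    }
    g[GATE_KEYS]
  })
  structure(
    list(name = name, erev_mv = erev_mv, gbar_s_cm2 = gbar_s_cm2,
         gates = gates, gbar_slope_per_um = gbar_slope_per_um),
    class = "channel_model"
  )
}

#' Gate steady state and time constant
#'
#' @param gate A gate parameter list (element of `channel$gates`).
#' @param v Membrane potential(s), mV.
#' @return Numeric vector.
#' @export
gate_inf <- function(gate, v) {
  1 / (1 + exp(-(v - gate$inf_vhalf_mv) / gate$inf_k_mv))
}

#' @rdname gate_inf
#' @export
gate_tau <- function(gate, v) {
  gate$tau_min_ms + gate$tau_amp_ms /
    (exp((v - gate$tau_vhalf_mv) / gate$tau_ka_mv) +
       exp(-(v - gate$tau_vhalf_mv) / gate$tau_kb_mv))
}

#' Channel current density
#'
#' `i = gbar * prod(gate^exponent) * (V - Erev)` in mA/cm^2.
#'
#' @param channel A [channel_model()].
#' @param v Membrane potential (mV).
#' @param gate_states Numeric vector of gate values in `[0, 1]`, one per
#'   gate, in the channel's gate order.
#' @param kind Compartment kind selecting the conductance density (default
#'   the first entry of the density map).
#' @return Current density (mA/cm^2); positive outward.
#' @export
channel_current <- function(channel, v, gate_states,
                            kind = names(channel$gbar_s_cm2)[1]) {
  stopifnot(length(gate_states) == length(channel$gates),
            all(gate_states >= 0 & gate_states <= 1))
  g <- unname(channel$gbar_s_cm2[kind])
  if (is.na(g)) g <- 0
  open <- 1
  for (i in seq_along(channel$gates)) {
    open <- open * gate_states[i]^channel$gates[[i]]$exponent
  }
  g * open * (v - channel$erev_mv)
}

#' Gate relaxation derivative
#'
#' `dx/dt = (x_inf(V) - x) / tau_x(V)` in 1/ms.
#'
#' @inheritParams channel_current
#' @param gate_index Which gate of the channel.
#' @param state Current gate value in `[0, 1]`.
#' @export
gate_derivative <- function(channel, gate_index, v, state) {
  stopifnot(state >= 0, state <= 1)
  g <- channel$gates[[gate_index]]
  (gate_inf(g, v) - state) / gate_tau(g, v)
}

#' Membrane model: passive constants plus a channel set
#'
#' @param passive A [passive_properties()].
#' @param channels List of [channel_model()] objects (empty for a purely
#'   passive membrane).
#' @param name Model name.
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(passive = passive_properties(), channels = list(),
                           name = "custom") {
  stopifnot(inherits(passive, "passive_properties"),
            all(vapply(channels, inherits, TRUE, "channel_model")))
  structure(list(name = name, passive = passive, channels = channels),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf(
    "<membrane_model '%s'> Rm = %g kOhm cm^2, Ra = %g Ohm cm, Cm = %g uF/cm^2, Vrest = %g mV (tau_m = %g ms)\n",
    x$name, x$passive$rm_kohm_cm2, x$passive$ra_ohm_cm, x$passive$cm_uf_cm2,
    x$passive$vrest_mv, x$passive$tau_m_ms))
  for (ch in x$channels) {
    cat(sprintf("  %s: Erev = %g mV, gates [%s], gbar(%s)\n", ch$name,
                ch$erev_mv,
                paste(vapply(ch$gates, `[[`, "", "name"), collapse = ", "),
                paste(sprintf("%s=%g", names(ch$gbar_s_cm2), ch$gbar_s_cm2),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Passive-only membrane with the default constants
#'
#' @param ... Passed to [passive_properties()].
#' @export
passive_membrane <- function(...) {
  membrane_model(passive_properties(...), channels = list(),
                 name = "passive")
}

#' The shipped CA1-like membrane configuration
#'
#' Loads the default active membrane: fast Na (axon/soma) and a dendritic Na
#' variant with weaker, slower inactivation, delayed-rectifier K, transient
#' A-type K concentrated in the dendrites, and a small hyperpolarization-
#' activated mixed current (Ih).
#'
#' @return A [membrane_model()].
#' @export
default_membrane <- function() {
  load_membrane_config(system.file("extdata", "ca1_membrane.yaml",
                                   package = "menpstim", mustWork = TRUE))
}

PASSIVE_KEYS <- c("rm_kohm_cm2", "ra_ohm_cm", "cm_uf_cm2", "vrest_mv",
                  "tau_m_ms")
CHANNEL_KEYS <- c("name", "erev_mv", "gbar_s_cm2", "gates",
                  "gbar_slope_per_um")

#' Read / write a membrane configuration file
#'
#' Structured YAML with a `passive` block (keys `rm_kohm_cm2`, `ra_ohm_cm`,
#' `cm_uf_cm2`, `vrest_mv`, optional `tau_m_ms`) and a `channels` list (see
#' [channel_model()] for the per-channel keys). Unknown keys are rejected;
#' an explicit `tau_m_ms` inconsistent with `Rm * Cm` is an error.
#'
#' @param path File path.
#' @return A [membrane_model()].
#' @export
load_membrane_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), c("name", "passive", "channels"))
  if (length(extra) > 0) {
    stop("unknown top-level key(s) in membrane config: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$passive)) stop("membrane config needs a `passive` block",
                                 call. = FALSE)
  extra <- setdiff(names(raw$passive), PASSIVE_KEYS)
  if (length(extra) > 0) {
    stop("unknown passive key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  req <- setdiff(PASSIVE_KEYS, c("tau_m_ms", names(raw$passive)))
  if (length(req) > 0) {
    stop("missing passive key(s): ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  passive <- do.call(passive_properties, raw$passive)
  channels <- lapply(raw$channels, function(ch) {
    extra <- setdiff(names(ch), CHANNEL_KEYS)
    if (length(extra) > 0) {
      stop(sprintf("unknown key(s) in channel '%s': %s",
                   ch$name %||% "?", paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    channel_model(
      name = ch$name, erev_mv = ch$erev_mv,
      gbar_s_cm2 = unlist(ch$gbar_s_cm2),
      gates = ch$gates,
      gbar_slope_per_um = if (!is.null(ch$gbar_slope_per_um)) {
        unlist(ch$gbar_slope_per_um)
      }
    )
  })
  membrane_model(passive, channels, name = raw$name %||% "unnamed")
}

#' @rdname load_membrane_config
#' @param membrane A [membrane_model()].
#' @export
write_membrane_config <- function(membrane, path) {
  stopifnot(inherits(membrane, "membrane_model"))
  p <- membrane$passive
  out <- list(
    name = membrane$name,
    passive = list(rm_kohm_cm2 = p$rm_kohm_cm2, ra_ohm_cm = p$ra_ohm_cm,
                   cm_uf_cm2 = p$cm_uf_cm2, vrest_mv = p$vrest_mv,
                   tau_m_ms = p$tau_m_ms),
    channels = lapply(membrane$channels, function(ch) {
      gates <- lapply(ch$gates, function(g) {
        # quote names so YAML boolean-like strings ("n", "y") survive
        g$name <- structure(g$name, quoted = TRUE)
        g
      })
      out <- list(name = ch$name, erev_mv = ch$erev_mv,
                  gbar_s_cm2 = as.list(ch$gbar_s_cm2), gates = gates)
      if (!is.null(ch$gbar_slope_per_um)) {
        out$gbar_slope_per_um <- as.list(ch$gbar_slope_per_um)
      }
      out
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Resting state of a membrane on a morphology
#'
#' Initialises every gate at its steady-state value at `Vrest` and solves,
#' per segment, the leak reversal potential that makes the total steady
#' membrane current zero at `Vrest`, so that the resting potential is an
#' exact equilibrium of the model regardless of channel densities.
#'
#' @param membrane A [membrane_model()].
#' @param morph A [morphology()].
#' @return A list with `v0_mv` (per-node resting potential), `gates`
#'   (node x gate matrix of steady-state values), `gate_names`, and
#'   `e_leak_mv` (per-node solved leak reversal).
#' @export
resting_state <- function(membrane, morph) {
  segs <- morph$segments
  n <- nrow(segs)
  vrest <- membrane$passive$vrest_mv
  g_leak <- 1 / (membrane$passive$rm_kohm_cm2 * 1000)  # S/cm^2
  gate_names <- character(0)
  gates <- NULL
  i_rest <- numeric(n)  # mA/cm^2, outward positive
  dist <- node_path_distance(morph)
  for (ch in membrane$channels) {
    open <- rep(1, n)
    for (g in ch$gates) {
      x <- gate_inf(g, vrest)
      gates <- cbind(gates, rep(x, n))
      gate_names <- c(gate_names, paste(ch$name, g$name, sep = "."))
      open <- open * x^g$exponent
    }
    dens <- channel_density(ch, segs$kind, dist)
    i_rest <- i_rest + dens * open * (vrest - ch$erev_mv)
  }
  if (is.null(gates)) gates <- matrix(0, n, 0)
  e_leak <- vrest + i_rest / g_leak
  list(v0_mv = rep(vrest, n), gates = gates, gate_names = gate_names,
       e_leak_mv = e_leak)
}

# Per-node conductance density (S/cm^2) for one channel, applying the
# optional linear-in-distance rule.
channel_density <- function(channel, kinds, dist_um) {
  g <- unname(channel$gbar_s_cm2[kinds])
  g[is.na(g)] <- 0
  if (!is.null(channel$gbar_slope_per_um)) {
    s <- unname(channel$gbar_slope_per_um[kinds])
    s[is.na(s)] <- 0
    g <- g * pmax(0, 1 + s * dist_um)
  }
  g
}

# Path distance (um) of every node from the root node, along the tree.
node_path_distance <- function(morph) {
  segs <- morph$segments
  edges <- segment_edges(morph)
  n <- nrow(segs)
  half <- segs$length_um / 2
  adj <- vector("list", n)
  if (!is.null(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- rep(NA_real_, n)
  root_sec <- morph$sections$section_id[is.na(morph$sections$parent_id)]
  root <- segs$node_id[segs$section_id == root_sec][1]
  dist[root] <- 0
  queue <- root
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (is.na(dist[j])) {
        dist[j] <- dist[i] + half[i] + half[j]
        queue <- c(queue, j)
      }
    }
  }
  if (anyNA(dist)) stop("morphology segments are not connected",
                        call. = FALSE)
  dist
}
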