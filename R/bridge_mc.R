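#' Parameters of the counterion-bridging toy model
#'
#' A desk-scale lattice-free Metropolis model of the bridging /
#' overcharging mechanism. Particles carry \code{sites_per_particle}
#' negative unit-charge sites and move in a periodic membrane-plane box;
#' divalent ions diffuse in the same box and may occupy nearby sites.
#' Energies are in units of kT:
#' \itemize{
#'   \item \code{bind_energy_kT} per ion-site bond (negative favours
#'     binding);
#'   \item \code{bridge_energy_kT} per additional distinct particle an ion
#'     is bound to (negative: the salt-bridge payoff);
#'   \item \code{charge_penalty_kT} times the Coulomb self-energy proxy of
#'     every connected particle-ion complex, \code{q^2 / sqrt(m)} for a
#'     complex of m particles with net charge q (plus 4 per unbound ion).
#'     This rewards charge neutralization at intermediate ion load and
#'     makes overcharge superextensive at high load, capping cluster
#'     growth — the dispersal ingredient.
#' }
#'
#' Each site carries two coordination slots (a carboxylate group offers
#' two oxygens), so one site can engage two ions; the second engagement is
#' priced by \code{second_bind_energy_kT}.
#'
#' @param n_particles number of protein particles.
#' @param sites_per_particle negative sites per particle.
#' @param box_nm box edge lengths; length 2 (membrane plane, default) or 3.
#' @param ion_count number of ions (the concentration proxy).
#' @param bind_energy_kT,second_bind_energy_kT,bridge_energy_kT,charge_penalty_kT
#'   energies (kT); \code{second_bind_energy_kT} prices the second ion on an
#'   already occupied site (the overcharging step).
#' @param contact_radius_nm ions may bind sites of particles within this
#'   distance; bound pairs may not be stretched beyond it.
#' @param max_sites_per_ion coordination capacity of one ion (1..10).
#'   Default 2, the dominant carboxylate coordination multiplicity; higher
#'   caps let few ions neutralize many sites, which suppresses the
#'   overcharging channel.
#' @param move_sizes named numeric: \code{particle} and \code{ion} maximum
#'   displacement per move (nm).
#' @param allow_bridging structural ablation switch: when FALSE an ion may
#'   only occupy sites of a single particle, so shared-ion bridges (and
#'   hence clusters) cannot form.
#' @param n_sweeps Monte-Carlo sweeps.
#' @param sample_every record observables every this many sweeps.
#' @param seed integer seed.
#' @return object of class \code{toy_params}.
#' @export
toy_params <- function(n_particles = 12L, sites_per_particle = 4L,
                       box_nm = c(22, 22), ion_count = 30L,
                       bind_energy_kT = -4, second_bind_energy_kT = -2,
                       bridge_energy_kT = -2,
                       charge_penalty_kT = 0.08, contact_radius_nm = 1.5,
                       max_sites_per_ion = 2L, allow_bridging = TRUE,
                       move_sizes = c(particle = 1.0, ion = 2.0),
                       n_sweeps = 40000L, sample_every = 100L, seed = 1L) {
  if (!length(box_nm) %in% c(2L, 3L) || any(box_nm <= 0))
    stop_usage("box_nm must be 2 or 3 positive edges")
  if (contact_radius_nm <= 0 || contact_radius_nm >= min(box_nm) / 2)
    stop_usage("contact_radius_nm must be in (0, half min box edge)")
  if (n_particles < 1L || sites_per_particle < 1L || ion_count < 0L)
    stop_usage("counts must be positive (ion_count may be 0)")
  if (max_sites_per_ion < 1L || max_sites_per_ion > 10L)
    stop_usage("max_sites_per_ion must be in 1..10")
  if (!all(is.finite(c(bind_energy_kT, second_bind_energy_kT,
                       bridge_energy_kT, charge_penalty_kT))))
    stop_usage("energies must be finite")
  structure(list(n_particles = as.integer(n_particles),
                 sites_per_particle = as.integer(sites_per_particle),
                 box_nm = box_nm, ion_count = as.integer(ion_count),
                 bind_energy_kT = bind_energy_kT,
                 second_bind_energy_kT = second_bind_energy_kT,
                 bridge_energy_kT = bridge_energy_kT,
                 charge_penalty_kT = charge_penalty_kT,
                 contact_radius_nm = contact_radius_nm,
                 max_sites_per_ion = as.integer(max_sites_per_ion),
                 allow_bridging = isTRUE(allow_bridging),
                 move_sizes = move_sizes,
                 n_sweeps = as.integer(n_sweeps),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "toy_params")
}

#' Reference parameter set of the bridging demonstrator
#'
#' The documented configuration (bundled as
#' \code{inst/extdata/mc_reference.json}) under which the model exhibits
#' its biphasic cluster-size curve across
#' \code{ion_counts = c(2, 30, 120)}.
#'
#' @param ... overrides passed to \code{\link{toy_params}}.
#' @return a \code{toy_params}.
#' @export
mc_reference_params <- function(...) {
  cfg <- jsonlite::read_json(system.file("extdata", "mc_reference.json",
                                         package = "ionbridge",
                                         mustWork = TRUE),
                             simplifyVector = TRUE)
  args <- cfg$params
  args$box_nm <- as.numeric(args$box_nm)
  args$move_sizes <- unlist(args$move_sizes)
  over <- list(...)
  args[names(over)] <- over
  do.call(toy_params, args)
}

#' Run the Metropolis sampler
#'
#' One seeded, fully reproducible trajectory of the toy model: particle and
#' ion displacement moves plus symmetric bind/unbind proposals, with
#' Metropolis acceptance on the total energy. The running energy is
#' accumulated from per-move increments and checked against a final
#' from-scratch recomputation.
#'
#' @param params a \code{\link{toy_params}}.
#' @return object of class \code{mc_result}: \code{observables}
#'   (data.frame sweep, energy_kT, n_bound, largest_cluster,
#'   mean_cluster), \code{state} (particle/ion positions, site occupancy
#'   map site -> ion index or NA), \code{acceptance} rates per move type,
#'   \code{energy_bookkeeping_error_kT} and \code{params}.
#' @export
run_mc <- function(params) {
  stopifnot(inherits(params, "toy_params"))
  ndim <- length(params$box_nm)
  np <- params$n_particles; ni <- params$ion_count
  res <- with_seed(params$seed, {
    p0 <- matrix(runif(np * ndim) * rep(params$box_nm, each = np), np, ndim)
    i0 <- if (ni > 0)
      matrix(runif(ni * ndim) * rep(params$box_nm, each = ni), ni, ndim)
    else matrix(0, 1L, ndim)
    .mc_run_cpp(np, params$sites_per_particle, ni, ndim,
                as.numeric(params$box_nm), p0, i0,
                params$bind_energy_kT, params$second_bind_energy_kT,
                params$bridge_energy_kT,
                params$charge_penalty_kT, params$contact_radius_nm,
                params$max_sites_per_ion,
                unname(params$move_sizes["particle"]),
                unname(params$move_sizes["ion"]),
                params$n_sweeps, params$sample_every,
                params$allow_bridging)
  })
  obs <- as.data.frame(res$observables)
  names(obs) <- c("sweep", "energy_kT", "n_bound", "largest_cluster",
                  "mean_cluster")
  structure(list(observables = obs,
                 state = list(particle_xy = res$particle_xy,
                              ion_xy = if (ni > 0) res$ion_xy else
                                res$ion_xy[0, , drop = FALSE],
                              site_bond = res$site_bond,
                              box_nm = params$box_nm),
                 acceptance = res$acceptance,
                 energy_bookkeeping_error_kT =
                   abs(res$energy_running - res$energy_recomputed),
                 params = params),
            class = "mc_result")
}

#' Partition particles into bridge-connected clusters
#'
#' Two particles belong to the same cluster when they share a bridging ion
#' (an ion bound to sites of both); optionally also when their centres lie
#' within a direct contact distance. Components are found with union-find.
#'
#' @param state the \code{state} element of an \code{\link{run_mc}} result
#'   (or a list with \code{particle_xy}, \code{site_bond}, \code{box_nm});
#'   \code{site_bond} may be a vector (one slot per site) or a matrix with
#'   one column per slot.
#' @param sites_per_particle sites per particle (site k belongs to particle
#'   \code{(k-1) \%/\% sites_per_particle + 1}).
#' @param direct_contact_nm optional centre-to-centre distance that also
#'   links particles (NULL: ion bridges only).
#' @return list: \code{membership} (cluster id per particle) and
#'   \code{sizes} (decreasing component sizes).
#' @export
cluster_partition <- function(state, sites_per_particle,
                              direct_contact_nm = NULL) {
  np <- nrow(state$particle_xy)
  parent <- seq_len(np)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  sb <- state$site_bond
  if (length(sb)) {
    sb <- cbind(sb)
    site_of <- rep(seq_len(nrow(sb)), ncol(sb))
    part_of <- (site_of - 1L) %/% sites_per_particle + 1L
    sbv <- as.vector(sb)
    for (u in unique(sbv[!is.na(sbv)])) {
      ps <- unique(part_of[!is.na(sbv) & sbv == u])
      if (length(ps) > 1L) for (k in 2:length(ps)) union2(ps[1L], ps[k])
    }
  }
  if (!is.null(direct_contact_nm) && np > 1L) {
    xy <- state$particle_xy
    box <- state$box_nm
    for (a in 1:(np - 1L)) for (b in (a + 1L):np) {
      d <- xy[a, ] - xy[b, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) < direct_contact_nm) union2(a, b)
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  membership <- match(roots, unique(roots))
  list(membership = membership,
       sizes = sort(unname(table(membership)), decreasing = TRUE))
}

#' Cluster-size curve versus ion count
#'
#' Runs the sampler at each ion count for several seeds, averages the
#' largest-cluster and mean-cluster observables over the equilibrated
#' second half of each run, and summarizes across seeds (mean and standard
#' error) — the biphasic-curve readout of the model.
#'
#' @param params base \code{\link{toy_params}} (its \code{ion_count} is
#'   overridden).
#' @param ion_counts integer vector of ion counts (>= 3 values spanning
#'   low, intermediate and high load).
#' @param seeds integer vector of seeds (>= 4 recommended, echoing
#'   multi-copy runs).
#' @return data.frame: ion_count, mean_largest, se_largest, mean_size,
#'   se_size, drift_warning (logical: observable still drifting over the
#'   second half).
#' @export
biphasic_scan <- function(params, ion_counts, seeds = 1:4) {
  if (length(ion_counts) < 3L)
    stop_usage("need at least 3 ion counts (low / intermediate / high)")
  rows <- lapply(ion_counts, function(nion) {
    largest <- size <- drift <- numeric(length(seeds))
    for (k in seq_along(seeds)) {
      p <- params
      p$ion_count <- as.integer(nion)
      p$seed <- as.integer(seeds[k])
      r <- run_mc(p)
      o <- r$observables
      half <- o[o$sweep > max(o$sweep) / 2, ]
      largest[k] <- mean(half$largest_cluster)
      size[k] <- mean(half$mean_cluster)
      q3 <- half[seq_len(nrow(half) / 2), ]
      q4 <- half[-seq_len(nrow(half) / 2), ]
      pooled_se <- sqrt(sd(q3$mean_cluster)^2 / nrow(q3) +
                          sd(q4$mean_cluster)^2 / nrow(q4))
      drift[k] <- abs(mean(q4$mean_cluster) - mean(q3$mean_cluster)) >
        3 * max(pooled_se, 1e-9) + 0.05
    }
    data.frame(ion_count = nion,
               mean_largest = mean(largest),
               se_largest = sd(largest) / sqrt(length(seeds)),
               mean_size = mean(size),
               se_size = sd(size) / sqrt(length(seeds)),
               drift_warning = any(drift > 0))
  })
  out <- do.call(rbind, rows)
  if (any(out$drift_warning))
    warning("observable drift over the second half at ion counts: ",
            paste(out$ion_count[out$drift_warning], collapse = ", "),
            call. = FALSE)
  out
}
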