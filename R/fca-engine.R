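#' Simulation configuration
#'
#' Constants of the guarded firing rule and the steady-state detector.
#' A state is declared steady at step `t >= steady_window` when every
#' species satisfies `|C_j,t - C_j,t-window| <= steady_tol`. A reaction
#' fires only when its limiting (minimum-concentration) product is below
#' its limiting reactant and its speed is below `firing_cap_fraction`
#' times the limiting reactant concentration.
#'
#' @param max_steps Maximum number of simulation steps (default 10000).
#' @param steady_window Look-back window of the steady test (default 5).
#' @param steady_tol Per-species absolute tolerance (default 0.001).
#' @param firing_cap_fraction Speed cap as a fraction of the limiting
#'   reactant concentration (default 0.75).
#' @param record_trajectory Keep the full per-step state (and per-step
#'   fired speeds) in the result.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(max_steps = 10000L, steady_window = 5L,
                       steady_tol = 0.001, firing_cap_fraction = 0.75,
                       record_trajectory = FALSE) {
  stopifnot(max_steps >= 1, steady_window >= 1, steady_tol > 0,
            firing_cap_fraction > 0)
  structure(list(max_steps = as.integer(max_steps),
                 steady_window = as.integer(steady_window),
                 steady_tol = steady_tol,
                 firing_cap_fraction = firing_cap_fraction,
                 record_trajectory = isTRUE(record_trajectory)),
            class = "sim_config")
}

## Precompile a model into integer-indexed reaction records over a state
## vector, so the sequential inner loop avoids name lookups.
compile_model <- function(model) {
  validate_model(model)
  sp_ids <- names(model$species)
  state0 <- vapply(model$species, function(s) s$concentration, numeric(1))
  names(state0) <- sp_ids
  rx <- lapply(model$reactions, function(r) {
    inh <- r$inhibitors
    list(
      id = r$id,
      ridx = match(r$reactants, sp_ids),
      pidx = match(r$products, sp_ids),
      eidx = match(r$enzymes, sp_ids),
      ## guard source: reactants when present, else the templates/enzymes
      gidx = if (length(r$reactants)) match(r$reactants, sp_ids)
             else match(r$enzymes, sp_ids),
      ## inhibitors kept in table order; a fixed conc (drug dose) takes
      ## precedence over the species-state lookup
      inh_idx = match(inh$ref, sp_ids),
      inh_ikd = inh$iKd,
      inh_fix = inh$conc,
      k = r$k,
      eKd = r$eKd
    )
  })
  list(sp_ids = sp_ids, state0 = state0, rx = rx,
       rx_ids = vapply(rx, `[[`, character(1), "id"))
}

## One sequential pass over all reactions; reaction i sees reaction
## (i-1)'s updates. The speed is accumulated in the formula's own factor
## order (k, reactants, enzymes, inhibitors, then the eKd division).
## Returns the new state and per-reaction fired speeds (0 when the
## guards blocked firing).
fire_reactions <- function(compiled, state, cap) {
  rxs <- compiled$rx
  n <- length(rxs)
  speeds <- numeric(n)
  for (i in seq_len(n)) {
    r <- rxs[[i]]
    gidx <- r$gidx
    if (!length(gidx)) next
    ## factor-by-factor accumulation in the formula's own order, so the
    ## result is bit-identical to a literal transcription of the rule
    s <- r$k
    for (j in r$ridx) s <- s * state[j]
    for (j in r$eidx) s <- s * state[j]
    for (j in seq_along(r$inh_ikd)) {
      ci <- r$inh_fix[j]
      if (is.na(ci)) ci <- state[r$inh_idx[j]]
      if (ci > 0) s <- s * (r$inh_ikd[j] / ci)
    }
    if (!is.na(r$eKd)) s <- s / r$eKd
    lim <- min(state[gidx])
    pmin_ <- if (length(r$pidx)) min(state[r$pidx]) else 0
    if (pmin_ < lim && s < cap * lim) {
      if (length(r$pidx)) state[r$pidx] <- state[r$pidx] + s
      if (length(r$ridx)) state[r$ridx] <- state[r$ridx] - s
      speeds[i] <- s
    }
  }
  if (any(state < 0))
    stop("internal invariant violation: negative concentration after firing")
  list(state = state, speeds = speeds)
}

#' Mass-action speed of a single reaction
#'
#' Evaluates `S = k * prod([reactants]) * prod([enzymes]) *
#' prod(iKd/[I]) / eKd` against a concentration state. Absent enzymes
#' contribute a factor of 1; an inhibitor with zero (or absent)
#' concentration contributes a factor of 1; an absent `eKd` behaves as 1.
#' Species-linked inhibitors read their concentration from `state`,
#' drug inhibitors use their fixed annotated concentration.
#'
#' @param reaction A [reaction()].
#' @param state Named numeric vector of species concentrations.
#' @return The non-negative speed.
#' @export
reaction_speed <- function(reaction, state) {
  stopifnot(inherits(reaction, "fnm_reaction"))
  if (any(state < 0, na.rm = TRUE))
    stop("internal invariant violation: negative concentration in state")
  conc_of <- function(id) {
    v <- state[id]
    if (is.na(v)) stop("unresolvable species reference: ", id)
    v
  }
  s <- reaction$k
  for (a in reaction$reactants) s <- s * conc_of(a)
  for (e in reaction$enzymes) s <- s * conc_of(e)
  inh <- reaction$inhibitors
  for (j in seq_len(nrow(inh))) {
    ci <- inh$conc[j]
    if (is.na(ci)) ci <- if (inh$ref[j] %in% names(state))
      state[[inh$ref[j]]] else 0
    if (ci > 0) s <- s * (inh$iKd[j] / ci)
  }
  if (!is.na(reaction$eKd)) s <- s / reaction$eKd
  unname(s)
}

#' Advance the simulation by one step
#'
#' Processes every reaction once, sequentially in the pinned (id-sorted)
#' order; each reaction fires only if the limiting product concentration
#' is below the limiting reactant concentration and the speed is below
#' `firing_cap_fraction` times the limiting reactant concentration.
#' Firing adds the speed to every product and subtracts it from every
#' consumed reactant; enzymes and templates are untouched. For reactions
#' without consumed reactants (template-driven transcription/translation,
#' activation) the guards read the templates/enzymes instead, and an
#' empty product set compares as 0 so pure sinks (decay) always pass the
#' first guard.
#'
#' @param model A [molecular_model()].
#' @param state Named numeric concentration vector covering every species
#'   of the model (defaults to the model's initial concentrations).
#' @param config A [sim_config()].
#' @return A list with `state` (the next concentrations) and `speeds`
#'   (named per-reaction fired speeds; 0 where guards blocked firing).
#' @export
fca_step <- function(model, state = NULL, config = sim_config()) {
  compiled <- compile_model(model)
  if (is.null(state)) state <- compiled$state0
  state <- state[compiled$sp_ids]
  if (anyNA(state)) stop("state does not cover every model species")
  out <- fire_reactions(compiled, state, config$firing_cap_fraction)
  names(out$state) <- compiled$sp_ids
  names(out$speeds) <- compiled$rx_ids
  out
}

#' Simulate a model to steady state
#'
#' Iterates the firing rule until, for every species,
#' `|C_j,t - C_j,t-window| <= steady_tol` (checked from
#' `t = steady_window` on), or until `max_steps` is exhausted, in which
#' case the result is flagged `reached_steady = FALSE` rather than
#' raising an error.
#'
#' @param model An initialized [molecular_model()].
#' @param config A [sim_config()].
#' @return An object of class `fca_sim`: a list with `final` (named
#'   concentrations), `final_speeds` (per-reaction speeds fired at the
#'   last step), `steps_taken`, `reached_steady`, and — when
#'   `config$record_trajectory` — `trajectory` (steps+1 x species matrix,
#'   row 1 the initial state) and `speed_trajectory` (steps x reactions).
#' @export
simulate_to_steady <- function(model, config = sim_config()) {
  compiled <- compile_model(model)
  n_sp <- length(compiled$sp_ids)
  w <- config$steady_window
  state <- compiled$state0
  ## ring buffer of the last (window+1) states for the steady test
  hist <- matrix(rep(state, w + 1L), nrow = n_sp)
  traj <- NULL; straj <- NULL
  if (config$record_trajectory) {
    traj <- matrix(NA_real_, nrow = config$max_steps + 1L, ncol = n_sp,
                   dimnames = list(NULL, compiled$sp_ids))
    traj[1L, ] <- state
    straj <- matrix(NA_real_, nrow = config$max_steps,
                    ncol = length(compiled$rx),
                    dimnames = list(NULL, compiled$rx_ids))
  }
  reached <- FALSE
  t <- 0L
  speeds <- numeric(length(compiled$rx))
  while (t < config$max_steps) {
    t <- t + 1L
    out <- fire_reactions(compiled, state, config$firing_cap_fraction)
    state <- out$state
    speeds <- out$speeds
    slot <- (t %% (w + 1L)) + 1L
    hist[, slot] <- state
    if (config$record_trajectory) {
      traj[t + 1L, ] <- state
      straj[t, ] <- speeds
    }
    if (t >= w) {
      back <- ((t - w) %% (w + 1L)) + 1L
      if (all(abs(state - hist[, back]) <= config$steady_tol)) {
        reached <- TRUE
        break
      }
    }
  }
  names(state) <- compiled$sp_ids
  names(speeds) <- compiled$rx_ids
  res <- list(final = state, final_speeds = speeds, steps_taken = t,
              reached_steady = reached)
  if (config$record_trajectory) {
    res$trajectory <- traj[seq_len(t + 1L), , drop = FALSE]
    res$speed_trajectory <- straj[seq_len(t), , drop = FALSE]
  }
  structure(res, class = "fca_sim")
}

#' @export
print.fca_sim <- function(x, ...) {
  cat("Simulation:", x$steps_taken, "steps,",
      if (x$reached_steady) "reached steady state" else
        "max_steps exhausted (NOT steady)", "\n")
  invisible(x)
}

#' Flux Comparative Analysis
#'
#' Simulates an untreated (control) and a drug-treated copy of the same
#' initialized model to steady state and reports, per hallmark readout,
#' the fold change `P` = readout token count under treatment divided by
#' readout token count under control. `P < 1` means the treatment reduced
#' the hallmark flux. The summed final-step speed of reactions feeding
#' each readout is reported alongside as `flux_P`, the alternative
#' flux-based comparison.
#'
#' @param model An initialized [molecular_model()].
#' @param drug A [drug_spec()] (or the name of a built-in drug, see
#'   [builtin_drugs()]).
#' @param inhibitor_conc Administered inhibitor concentration, in the
#'   same nM units as the drug's dissociation constants (default 1).
#' @param readouts Readout species ids; defaults to the model's declared
#'   readouts.
#' @param config A [sim_config()].
#' @return An object of class `fca_result`: list with `P` (named numeric,
#'   `NA` where the control readout is 0), `flux_P`, `control` and
#'   `treatment` (`fca_sim` results), `drug`, `inhibitor_conc`, and
#'   `undefined` (readouts with zero control signal).
#' @export
run_fca <- function(model, drug, inhibitor_conc = 1,
                    readouts = model$readouts, config = sim_config()) {
  if (is.character(drug)) drug <- builtin_drugs()[[match.arg(drug, names(builtin_drugs()))]]
  if (!length(readouts)) stop("no readout components declared")
  control <- simulate_to_steady(model, config)
  treated_model <- apply_treatment(model, drug, inhibitor_conc)
  treatment <- simulate_to_steady(treated_model, config)
  if (!control$reached_steady || !treatment$reached_steady)
    warning("simulation did not reach steady state; P reported from final state")
  ctrl_v <- control$final[readouts]
  trt_v <- treatment$final[readouts]
  undefined <- readouts[ctrl_v <= 0]
  P <- ifelse(ctrl_v > 0, trt_v / ctrl_v, NA_real_)
  names(P) <- readouts
  flux_in <- function(sim) {
    vapply(readouts, function(ro) {
      feeds <- vapply(model$reactions, function(r) ro %in% r$products,
                      logical(1))
      sum(sim$final_speeds[names(model$reactions)[feeds]])
    }, numeric(1))
  }
  fc <- flux_in(control); ft <- flux_in(treatment)
  flux_P <- ifelse(fc > 0, ft / fc, NA_real_)
  structure(list(P = P, flux_P = flux_P, control = control,
                 treatment = treatment, drug = drug$name,
                 inhibitor_conc = inhibitor_conc, undefined = undefined),
            class = "fca_result")
}

#' @export
print.fca_result <- function(x, ...) {
  cat("Flux Comparative Analysis —", x$drug,
      sprintf("([I] = %g nM)\n", x$inhibitor_conc))
  for (ro in names(x$P)) {
    cat(sprintf("  %s: P = %s%s\n", ro,
                if (is.na(x$P[[ro]])) "undefined (control readout 0)"
                else fmt_num(x$P[[ro]]),
                if (!is.na(x$P[[ro]]) && x$P[[ro]] < 1) "  [responder]"
                else ""))
  }
  invisible(x)
}
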