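# Compile a validated ModelNetwork into an explicit ODE system: pick state
# variables, orient every dependency causally, schedule algebraic evaluation
# topologically, and build a right-hand-side evaluator.

#' ODESystem: a compiled model network
#'
#' @slot network The source [ModelNetwork-class].
#' @slot states Ordered character vector of state property ids (amounts and
#'   momenta integrated by boundary dependencies).
#' @slot init Named numeric vector of initial state values.
#' @slot schedule `data.frame(dependency, output)`: the algebraic evaluation
#'   order (a topological order of the property-computation graph;
#'   transformer-type kinds contribute one row per causal output).
#' @slot internals Precompiled evaluation data (closures, accumulation table,
#'   parameter values); not part of the public contract.
#' @export
setClass("ODESystem",
         representation(network = "ModelNetwork", states = "character",
                        init = "numeric", schedule = "data.frame",
                        internals = "list"))

#' State variables of a network
#'
#' Every amount that a `boundary_flow` moves (as `source_player` or
#' `target_player`) and every momentum a `boundary_force` accumulates, ordered
#' by id. Each must carry an initial value.
#'
#' @param net A validated [ModelNetwork-class].
#' @return Character vector of property ids.
#' @export
identifyStates <- function(net) {
  states <- .stateProperties(net)
  for (pid in states)
    if (is.na(net@properties[[pid]]@value))
      physdepStop("E_NO_INITIAL", sprintf("state property '%s' has no initial value", pid), id = pid)
  states
}

#' Assign computational causality
#'
#' Orients every dependency: capacitive computes its high force, inductive and
#' the flow-rate kinds compute their flow, summation its whole, spatial and
#' transactor their target, transformer/transducer the pair
#' `(force_player_2, flow_player_1)`; boundary kinds compute state
#' derivatives. Verifies that every dynamical property is a state, a source, a
#' prescribed constant (a state-category property with a set value that
#' nothing computes), or the output of exactly one dependency.
#'
#' @param net A validated [ModelNetwork-class].
#' @return List with `states`, `outputs` (named character: property id ->
#'   computing dependency id), `depOutputs` (dependency id -> named character
#'   of role -> property id), and `fixed` (prescribed-constant property ids).
#' @export
assignCausality <- function(net) {
  states <- .stateProperties(net)
  sourceProps <- names(net@sources)
  outputs <- character(0)     # property -> dep id
  depOutputs <- list()
  for (d in net@dependencies) {
    k <- dependencyKind(d@kind)
    if (k$boundary) next
    outs <- character(0)
    for (role in k$outputs) {
      pid <- .boundTo(d, role)
      if (length(pid) != 1L)
        physdepStop("E_MISSING_ROLE",
                    sprintf("dependency '%s' must bind output role '%s' exactly once", d@id, role))
      outs[role] <- pid
      if (pid %in% states || pid %in% sourceProps || pid %in% names(outputs))
        physdepStop("E_OVERDETERMINED",
                    sprintf("property '%s' is computed more than once (dependency '%s')", pid, d@id),
                    id = pid)
      outputs[pid] <- d@id
    }
    depOutputs[[d@id]] <- outs
  }
  # every remaining dynamical property must be a prescribed constant
  fixed <- character(0)
  for (p in net@properties) {
    cat_ <- .propertyCategory(net, p@id)
    if (.categoryGroup(cat_) == "constitutive") next
    if (p@id %in% states || p@id %in% sourceProps || p@id %in% names(outputs)) next
    if (cat_ %in% c("amount", "momentum") && !is.na(p@value)) {
      fixed <- c(fixed, p@id)
    } else {
      physdepStop("E_UNDERDETERMINED",
                  sprintf("property '%s' (%s) is never computed and is not a state, source, or prescribed constant",
                          p@id, cat_), id = p@id)
    }
  }
  list(states = states, outputs = outputs, depOutputs = depOutputs, fixed = fixed)
}

# inputs of one (dependency, output role) schedule item: the dynamical
# properties that must be known before the item can run
.itemInputs <- function(net, d, role) {
  k <- dependencyKind(d@kind)
  if (d@kind %in% c("transformer", "transducer")) {
    inRole <- if (role == "force_player_2") "force_player_1" else "flow_player_2"
    return(.boundTo(d, inRole))
  }
  b <- d@bindings
  b$property[!(b$role %in% c("constitutive", k$outputs))]
}

#' Order the algebraic evaluation schedule
#'
#' Topologically sorts the (dependency, output) computation items; ties are
#' broken deterministically by dependency id then output property id. A cycle
#' among algebraic items (e.g. two resistive dependencies computing each
#' other's force inputs with no storage node between) raises
#' `E_ALGEBRAIC_LOOP` naming the dependencies on the cycle.
#'
#' @param net A validated [ModelNetwork-class].
#' @param causality Result of [assignCausality()]; computed when omitted.
#' @return `data.frame(dependency, output)` in evaluation order.
#' @export
buildSchedule <- function(net, causality = assignCausality(net)) {
  items <- list()
  for (did in names(causality$depOutputs)) {
    outs <- causality$depOutputs[[did]]
    for (role in names(outs))
      items[[length(items) + 1L]] <- list(dep = did, role = role, out = outs[[role]])
  }
  if (!length(items))
    return(data.frame(dependency = character(0), output = character(0)))
  key <- vapply(items, function(it) paste(it$dep, it$out), "")
  ord <- order(key)
  items <- items[ord]
  producer <- stats::setNames(seq_along(items), vapply(items, `[[`, "", "out"))
  n <- length(items)
  preds <- vector("list", n)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    ins <- .itemInputs(net, net@dependencies[[items[[i]]$dep]], items[[i]]$role)
    pre <- unname(producer[ins[ins %in% names(producer)]])
    preds[[i]] <- pre
    indeg[i] <- length(pre)
  }
  succs <- vector("list", n)
  for (i in seq_len(n)) for (p in preds[[i]]) succs[[p]] <- c(succs[[p]], i)
  ready <- which(indeg == 0L)
  sched <- integer(0)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]  # items are pre-sorted, so FIFO on the
    sched <- c(sched, i)                 # sorted index is the id tie-break
    for (s in succs[[i]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) ready <- sort(c(ready, s))
    }
  }
  if (length(sched) < n) {
    cyc <- sort(unique(vapply(items[setdiff(seq_len(n), sched)], `[[`, "", "dep")))
    physdepStop("E_ALGEBRAIC_LOOP",
                sprintf("algebraic loop among dependencies: %s", paste(cyc, collapse = ", ")),
                dependencies = cyc)
  }
  data.frame(dependency = vapply(items[sched], `[[`, "", "dep"),
             output = vapply(items[sched], `[[`, "", "out"),
             stringsAsFactors = FALSE)
}

# Build one evaluation closure per schedule item. Each closure takes the
# current named value vector and returns the output value.
.makeEvaluator <- function(net, d, role) {
  b <- function(r) .boundTo(d, r)
  p <- function(pid) net@properties[[pid]]@value
  switch(d@kind,
    resistive = {
      cst <- b("constitutive")
      R <- if (.propertyCategory(net, cst) == "constitutive.conductance") 1 / p(cst) else p(cst)
      hi <- b("force_player_high"); lo <- b("force_player_low")
      function(v, t) (v[[hi]] - v[[lo]]) / R
    },
    capacitive = {
      C <- p(b("constitutive")); am <- b("amount_player"); lo <- b("force_player_low")
      if (length(lo)) function(v, t) v[[am]] / C + v[[lo]]
      else function(v, t) v[[am]] / C
    },
    inductive = {
      L <- p(b("constitutive")); mo <- b("momentum_player")
      function(v, t) v[[mo]] / L
    },
    diffusion = {
      kd <- p(b("constitutive")); hi <- b("source_player"); lo <- b("target_player")
      function(v, t) kd * (v[[hi]] - v[[lo]])
    },
    mass_action = {
      ks <- b("constitutive")
      kf <- p(ks[1]); kr <- if (length(ks) > 1L) p(ks[2]) else 0
      fwd <- b("source_player"); rev <- b("target_player")
      stoich <- function(pid) {
        s <- d@params[paste0("stoich_", pid)]
        if (is.na(s)) 1 else s
      }
      sf <- vapply(fwd, stoich, 0); sr <- vapply(rev, stoich, 0)
      function(v, t) {
        a <- unlist(v[fwd], use.names = FALSE)
        r <- if (length(rev)) unlist(v[rev], use.names = FALSE) else numeric(0)
        if (any(a < -1e-9) || any(r < -1e-9))
          physdepStop("E_NEGATIVE_STATE",
                      sprintf("amount below -1e-9 in mass-action dependency '%s'", d@id))
        kf * prod(pmax(a, 0) ^ sf) - kr * prod(pmax(r, 0) ^ sr)
      }
    },
    michaelis_menten = {
      Vmax <- d@params[["Vmax"]]; Km <- d@params[["Km"]]; am <- b("amount_player")
      function(v, t) Vmax * v[[am]] / (Km + v[[am]])
    },
    summation = {
      parts <- b("part_player")
      function(v, t) sum(unlist(v[parts], use.names = FALSE))
    },
    spatial = {
      a <- if ("a" %in% names(d@params)) d@params[["a"]] else 1
      bb <- if ("b" %in% names(d@params)) d@params[["b"]] else 1
      src <- b("source_player")
      function(v, t) {
        x <- v[[src]]
        if (x < 0 && bb != round(bb))
          physdepStop("E_BAD_STATE",
                      sprintf("negative primary state with non-integer exponent in '%s'", d@id))
        a * x ^ bb
      }
    },
    transformer = ,
    transducer = {
      m <- p(b("constitutive"))
      if (role == "force_player_2") {
        f1 <- b("force_player_1"); function(v, t) m * v[[f1]]
      } else {
        f2 <- b("flow_player_2"); function(v, t) m * v[[f2]]
      }
    },
    transactor = {
      cc <- p(b("constitutive")); src <- b("source_player")
      function(v, t) cc * v[[src]]
    },
    physdepStop("E_SCHEMA", sprintf("no evaluator for kind '%s'", d@kind)))
}

#' Compile a model network to an ODE system
#'
#' Composes [identifyStates()], [assignCausality()], and [buildSchedule()],
#' then precompiles an evaluator per scheduled step and an accumulation table
#' mapping boundary dependencies onto state derivatives. Compilation is
#' deterministic: identical networks yield identical state orders and
#' schedules.
#'
#' @param net A [ModelNetwork-class] with no validation errors.
#' @return An [ODESystem-class].
#' @examples
#' sys <- compileNetwork(makeFixture("rc_circuit"))
#' odeStates(sys)
#' @export
compileNetwork <- function(net) {
  rep <- validateNetwork(net)
  errs <- rep[rep$level == "error", , drop = FALSE]
  if (nrow(errs))
    physdepStop("E_INVALID_NETWORK",
                paste0("network has validation errors:\n",
                       paste(sprintf("  [%s] %s: %s", errs$code, errs$subject, errs$message),
                             collapse = "\n")))
  causality <- assignCausality(net)
  states <- identifyStates(net)
  schedule <- buildSchedule(net, causality)

  evals <- vector("list", nrow(schedule))
  outRole <- character(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    d <- net@dependencies[[schedule$dependency[i]]]
    role <- names(causality$depOutputs[[d@id]])[
      causality$depOutputs[[d@id]] == schedule$output[i]]
    outRole[i] <- role
    evals[[i]] <- .makeEvaluator(net, d, role)
  }

  # accumulation: per state, signed contributions of flow/force properties
  accum <- stats::setNames(vector("list", length(states)), states)
  for (d in net@dependencies) {
    if (d@kind == "boundary_flow") {
      for (f in .boundTo(d, "flow_player")) {
        for (tg in .boundTo(d, "target_player"))
          accum[[tg]] <- rbind(accum[[tg]], data.frame(prop = f, sign = 1))
        for (sc in .boundTo(d, "source_player"))
          accum[[sc]] <- rbind(accum[[sc]], data.frame(prop = f, sign = -1))
      }
    } else if (d@kind == "boundary_force") {
      mo <- .boundTo(d, "momentum_player")
      for (f in .boundTo(d, "force_player_high"))
        accum[[mo]] <- rbind(accum[[mo]], data.frame(prop = f, sign = 1))
      for (f in .boundTo(d, "force_player_low"))
        accum[[mo]] <- rbind(accum[[mo]], data.frame(prop = f, sign = -1))
    }
  }

  propIds <- sort(names(net@properties))
  base <- stats::setNames(rep(NA_real_, length(propIds)), propIds)
  for (p in net@properties) {
    grp <- .categoryGroup(.propertyCategory(net, p@id))
    if (grp == "constitutive" || p@id %in% causality$fixed) base[p@id] <- p@value
  }

  new("ODESystem", network = net, states = states,
      init = stats::setNames(vapply(states, function(s) net@properties[[s]]@value, 0), states),
      schedule = schedule,
      internals = list(evals = evals, outRole = outRole, accum = accum,
                       base = base, sources = net@sources,
                       fixed = causality$fixed))
}

#' @rdname compileNetwork
#' @param sys An [ODESystem-class].
#' @export
odeStates <- function(sys) sys@states

#' @rdname compileNetwork
#' @export
odeSchedule <- function(sys) sys@schedule

#' Evaluate the compiled right-hand side
#'
#' Evaluates sources at `t`, runs the algebraic schedule, and accumulates net
#' flows/forces into state derivatives per the boundary dependencies.
#'
#' @param sys An [ODESystem-class].
#' @param t Time (s).
#' @param state Named (or ordered) numeric vector of state values.
#' @return List with `deriv` (named numeric, one per state) and `values`
#'   (named numeric over every property id).
#' @export
evalRHS <- function(sys, t, state) {
  v <- sys@internals$base
  v[sys@states] <- state
  for (s in sys@internals$sources) v[s@property] <- .sourceValue(s, t)
  evals <- sys@internals$evals
  outs <- sys@schedule$output
  for (i in seq_along(evals)) v[[outs[i]]] <- evals[[i]](v, t)
  deriv <- stats::setNames(numeric(length(sys@states)), sys@states)
  for (st in sys@states) {
    a <- sys@internals$accum[[st]]
    if (!is.null(a)) deriv[st] <- sum(v[a$prop] * a$sign)
  }
  list(deriv = deriv, values = v)
}

#' Human-readable equation listing of a compiled system
#'
#' One line per state derivative and per scheduled algebraic step.
#'
#' @param sys An [ODESystem-class].
#' @return Character vector of equation lines.
#' @export
equationListing <- function(sys) {
  net <- sys@network
  lines <- character(0)
  for (st in sys@states) {
    a <- sys@internals$accum[[st]]
    terms <- if (is.null(a)) "0" else
      paste(ifelse(a$sign > 0, "+", "-"), a$prop, collapse = " ")
    lines <- c(lines, sprintf("d(%s)/dt = %s", st, sub("^\\+ ", "", terms)))
  }
  for (i in seq_len(nrow(sys@schedule))) {
    d <- net@dependencies[[sys@schedule$dependency[i]]]
    lines <- c(lines, sprintf("%s = %s(%s)   # %s", sys@schedule$output[i], d@kind,
                              paste(setdiff(d@bindings$property, sys@schedule$output[i]),
                                    collapse = ", "), d@id))
  }
  lines
}

setMethod("show", "ODESystem", function(object) {
  cat(sprintf("ODESystem: %d state(s), %d scheduled step(s)\n",
              length(object@states), nrow(object@schedule)))
  cat(paste0("  ", equationListing(object), collapse = "\n"), "\n")
})
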