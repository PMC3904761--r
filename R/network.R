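# Network assembly and validation: resolve references, enforce per-kind role
# signatures and domain rules, and unroll dependencies into signed influence
# edges for qualitative reasoning.

.checkUnique <- function(ids, what) {
  d <- ids[duplicated(ids)]
  if (length(d))
    physdepStop("E_DUPLICATE_ID", sprintf("duplicate %s id(s): %s", what, paste(unique(d), collapse = ", ")))
}

#' Construct a ModelNetwork from component objects
#'
#' Checks id uniqueness and resolves every cross-reference (bearers, bindings,
#' part-of links, process participants, source properties); physics validity
#' (signatures, domains, constitutive positivity) is checked separately by
#' [validateNetwork()].
#'
#' @param entities,processes,properties,dependencies,sources Lists of the
#'   corresponding S4 objects (may be empty).
#' @param metadata List with `name` and `description`.
#' @return A [ModelNetwork-class].
#' @export
modelNetwork <- function(entities = list(), processes = list(), properties = list(),
                         dependencies = list(), sources = list(),
                         metadata = list(name = "model", description = "")) {
  nameBy <- function(xs, f) stats::setNames(xs, vapply(xs, f, ""))
  entities <- nameBy(entities, function(x) x@id)
  processes <- nameBy(processes, function(x) x@id)
  properties <- nameBy(properties, function(x) x@id)
  dependencies <- nameBy(dependencies, function(x) x@id)
  sources <- nameBy(sources, function(x) x@property)
  .checkUnique(names(entities), "entity")
  .checkUnique(names(processes), "process")
  .checkUnique(names(properties), "property")
  .checkUnique(names(dependencies), "dependency")
  .checkUnique(names(sources), "source")
  .checkUnique(c(names(entities), names(processes)), "entity/process")

  bearers <- c(names(entities), names(processes))
  for (p in properties)
    if (!p@bearer %in% bearers)
      physdepStop("E_UNRESOLVED_REF", sprintf("property '%s' bears on unknown node '%s'", p@id, p@bearer),
                  id = p@bearer)
  for (e in entities)
    if (!is.na(e@partOf) && !e@partOf %in% names(entities))
      physdepStop("E_UNRESOLVED_REF", sprintf("entity '%s' part_of unknown entity '%s'", e@id, e@partOf),
                  id = e@partOf)
  for (pr in processes)
    for (pt in pr@participants)
      if (!pt %in% names(entities))
        physdepStop("E_UNRESOLVED_REF", sprintf("process '%s' has unknown participant '%s'", pr@id, pt),
                    id = pt)
  for (d in dependencies) {
    dependencyKind(d@kind)  # E_SCHEMA if unknown
    for (pid in d@bindings$property)
      if (!pid %in% names(properties))
        physdepStop("E_UNRESOLVED_REF", sprintf("dependency '%s' binds unknown property '%s'", d@id, pid),
                    id = pid)
  }
  for (s in sources)
    if (!s@property %in% names(properties))
      physdepStop("E_UNRESOLVED_REF", sprintf("source drives unknown property '%s'", s@property),
                  id = s@property)
  for (p in properties) .propertyClassById(p@propClass)

  new("ModelNetwork", entities = entities, processes = processes,
      properties = properties, dependencies = dependencies,
      sources = sources, metadata = metadata)
}

#' Assemble a ModelNetwork from a parsed model description
#'
#' Takes the plain-list form of the YAML model dialect (see [readModel()]) and
#' builds the typed network, resolving all references. Unknown dependency
#' kinds raise `E_SCHEMA`; dangling references raise `E_UNRESOLVED_REF`;
#' duplicate ids raise `E_DUPLICATE_ID`.
#'
#' @param spec Named list with elements `entities`, `properties`,
#'   `dependencies` and optionally `processes`, `sources`, `metadata`.
#' @return A [ModelNetwork-class].
#' @export
assembleNetwork <- function(spec) {
  getf <- function(x, f, default = NULL) if (!is.null(x[[f]])) x[[f]] else default
  entities <- lapply(getf(spec, "entities", list()), function(e)
    entityNode(e$id, domain = e$domain, label = getf(e, "label", e$id),
               partOf = getf(e, "part_of", NA_character_)))
  processes <- lapply(getf(spec, "processes", list()), function(p)
    processNode(p$id, participants = as.character(unlist(p$participants)),
                label = getf(p, "label", p$id)))
  properties <- lapply(getf(spec, "properties", list()), function(p)
    propertyInstance(p$id, propClass = p$class, bearer = p$bearer,
                     value = getf(p, "value", NA_real_)))
  dependencies <- lapply(getf(spec, "dependencies", list()), function(d) {
    b <- do.call(rbind, lapply(d$bindings, function(x)
      data.frame(role = x$role, property = x$property, stringsAsFactors = FALSE)))
    if (is.null(b)) b <- data.frame(role = character(0), property = character(0))
    dependencyInstance(d$id, kind = d$kind, bindings = b,
                       params = unlist(getf(d, "params", list())))
  })
  sources <- lapply(getf(spec, "sources", list()), function(s)
    sourceSpec(s$property, waveform = getf(s, "waveform", "constant"),
               level = getf(s, "level", 0), tStep = getf(s, "t_step", 0),
               amplitude = getf(s, "amplitude", 0), period = getf(s, "period", 1),
               phase = getf(s, "phase", 0)))
  meta <- getf(spec, "metadata", list())
  modelNetwork(entities, processes, properties, dependencies, sources,
               metadata = list(name = getf(meta, "name", "model"),
                               description = getf(meta, "description", "")))
}

.finding <- function(level, code, subject, message)
  data.frame(level = level, code = code, subject = subject, message = message,
             stringsAsFactors = FALSE)

.emptyReport <- function()
  data.frame(level = character(0), code = character(0), subject = character(0),
             message = character(0), stringsAsFactors = FALSE)

# part_of must form a forest
.partOfCycles <- function(net) {
  out <- list()
  for (e in net@entities) {
    seen <- character(0); cur <- e@id
    repeat {
      parent <- net@entities[[cur]]@partOf
      if (is.na(parent)) break
      if (parent %in% c(seen, cur)) { out[[length(out) + 1L]] <- e@id; break }
      seen <- c(seen, cur); cur <- parent
    }
  }
  unique(unlist(out))
}

#' Validate a model network against the dependency-kind signatures
#'
#' Checks every dependency instance against its kind's role signature
#' (declared roles, multiplicities, player categories), domain rules
#' (single-domain kinds homogeneous; transducers spanning exactly two
#' domains; transactor mismatches downgraded to warnings), constitutive value
#' positivity, source categories, part-of acyclicity, and initial values for
#' boundary-driven states. Findings are returned as data, never thrown, and
#' the report is deterministic (ordered by subject id, then code).
#'
#' @param net A [ModelNetwork-class].
#' @return A `data.frame` with columns `level` (`"error"`/`"warning"`),
#'   `code`, `subject`, `message`. Zero error rows means the network is
#'   physics-valid and will compile or fail only with scheduling errors.
#' @export
validateNetwork <- function(net) {
  fs <- list()
  add <- function(level, code, subject, message)
    fs[[length(fs) + 1L]] <<- .finding(level, code, subject, message)

  for (cyc in .partOfCycles(net))
    add("error", "E_CYCLIC_PARTS", cyc, "part_of references form a cycle")

  for (d in net@dependencies) {
    k <- dependencyKind(d@kind)
    for (role in unique(d@bindings$role))
      if (!role %in% names(k$roles))
        add("error", "E_UNKNOWN_ROLE", d@id,
            sprintf("role '%s' is not declared by kind '%s'", role, d@kind))
    for (role in names(k$roles)) {
      sig <- k$roles[[role]]
      bound <- .boundTo(d, role)
      if (length(bound) < sig$min)
        add("error", "E_MISSING_ROLE", d@id,
            sprintf("kind '%s' requires at least %d '%s' binding(s), found %d",
                    d@kind, sig$min, role, length(bound)))
      if (length(bound) > sig$max)
        add("error", "E_EXTRA_ROLE", d@id,
            sprintf("kind '%s' allows at most %s '%s' binding(s), found %d",
                    d@kind, format(sig$max), role, length(bound)))
      for (pid in bound) {
        cat_ <- .propertyCategory(net, pid)
        if (!cat_ %in% sig$categories)
          add("error", "E_WRONG_CATEGORY", d@id,
              sprintf("property '%s' bound to role '%s' has category '%s', expected one of: %s",
                      pid, role, cat_, paste(sig$categories, collapse = ", ")))
      }
    }
    if (d@kind == "boundary_flow" &&
        length(.boundTo(d, "source_player")) + length(.boundTo(d, "target_player")) == 0L)
      add("error", "E_MISSING_ROLE", d@id,
          "boundary_flow requires a source_player and/or target_player amount")

    # domain rules over dynamical (non-constitutive) players
    dynB <- d@bindings[d@bindings$role != "constitutive", , drop = FALSE]
    dynB <- dynB[dynB$property %in% names(net@properties), , drop = FALSE]
    doms <- vapply(dynB$property, function(p) .propertyDomain(net, p), "")
    if (k$domainRule == "single" && length(unique(doms)) > 1L)
      add("error", "E_DOMAIN_MISMATCH", d@id,
          sprintf("kind '%s' is single-domain but players span: %s",
                  d@kind, paste(sort(unique(doms)), collapse = ", ")))
    if (k$domainRule == "two") {
      side1 <- doms[dynB$role %in% c("force_player_1", "flow_player_1")]
      side2 <- doms[dynB$role %in% c("force_player_2", "flow_player_2")]
      ok <- length(unique(side1)) == 1L && length(unique(side2)) == 1L &&
        !identical(unique(side1), unique(side2))
      if (!ok)
        add("error", "E_DOMAIN_MISMATCH", d@id,
            "transducer players must span exactly two domains, one per side")
    }
    if (d@kind == "transactor" && length(unique(doms)) > 1L)
      add("warning", "E_DOMAIN_MISMATCH", d@id,
          sprintf("transactor couples domains: %s (wild-card dependency, allowed)",
                  paste(sort(unique(doms)), collapse = ", ")))

    # constitutive values
    for (pid in .boundTo(d, "constitutive")) {
      if (!pid %in% names(net@properties)) next
      v <- net@properties[[pid]]@value
      cat_ <- .propertyCategory(net, pid)
      if (is.na(v))
        add("error", "E_BAD_CONSTITUTIVE", d@id,
            sprintf("constitutive property '%s' has no value", pid))
      else if (cat_ != "constitutive.coefficient" && v <= 0)
        add("error", "E_BAD_CONSTITUTIVE", d@id,
            sprintf("constitutive property '%s' must be > 0, is %g", pid, v))
    }
    if (d@kind == "mass_action") {
      st <- d@params[grepl("^stoich_", names(d@params))]
      for (i in seq_along(st))
        if (st[i] <= 0 || st[i] != round(st[i]))
          add("error", "E_BAD_VALUE", d@id,
              sprintf("stoichiometry '%s' must be a positive integer", names(st)[i]))
    }
    if (d@kind == "michaelis_menten") {
      for (pn in c("Vmax", "Km"))
        if (is.na(d@params[pn]) || d@params[pn] <= 0)
          add("error", "E_BAD_CONSTITUTIVE", d@id,
              sprintf("michaelis_menten requires parameter '%s' > 0", pn))
    }
  }

  for (s in net@sources) {
    cat_ <- .propertyCategory(net, s@property)
    if (!cat_ %in% c("force", "flow"))
      add("error", "E_BAD_SOURCE", s@property,
          sprintf("source property '%s' has category '%s'; sources must drive a force or flow", s@property, cat_))
  }

  # boundary-driven states need initial values
  for (pid in .stateProperties(net))
    if (is.na(net@properties[[pid]]@value))
      add("error", "E_NO_INITIAL", pid,
          sprintf("state property '%s' is integrated but has no initial value", pid))

  rep <- if (length(fs)) do.call(rbind, fs) else .emptyReport()
  rep <- rep[order(rep$subject, rep$code, rep$message), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

# state properties: amounts moved by boundary_flow, momenta by boundary_force
.stateProperties <- function(net) {
  out <- character(0)
  for (d in net@dependencies) {
    if (d@kind == "boundary_flow")
      out <- c(out, .boundTo(d, "source_player"), .boundTo(d, "target_player"))
    if (d@kind == "boundary_force")
      out <- c(out, .boundTo(d, "momentum_player"))
  }
  sort(unique(out[out %in% names(net@properties)]))
}

.signOf <- function(x) if (x > 0) "+" else if (x < 0) "-" else "0"

# signed influence edges of one dependency under compiled causality
.depEdges <- function(net, d) {
  E <- function(from, to, sign) data.frame(from = from, to = to, sign = sign,
                                           stringsAsFactors = FALSE)
  b <- function(role) .boundTo(d, role)
  out <- list()
  push <- function(df) out[[length(out) + 1L]] <<- df
  switch(d@kind,
    resistive = {
      push(E(b("force_player_high"), b("flow_player"), "+"))
      push(E(b("force_player_low"), b("flow_player"), "-"))
    },
    capacitive = {
      push(E(b("amount_player"), b("force_player_high"), "+"))
      fl <- b("force_player_low")
      if (length(fl)) push(E(fl, b("force_player_high"), "+"))
    },
    inductive = push(E(b("momentum_player"), b("flow_player"), "+")),
    diffusion = {
      push(E(b("source_player"), b("flow_player"), "+"))
      push(E(b("target_player"), b("flow_player"), "-"))
    },
    mass_action = {
      for (p in b("source_player")) push(E(p, b("flow_player"), "+"))
      for (p in b("target_player")) push(E(p, b("flow_player"), "-"))
    },
    michaelis_menten = push(E(b("amount_player"), b("flow_player"), "+")),
    summation = for (p in b("part_player")) push(E(p, b("whole_player"), "+")),
    spatial = {
      a <- if ("a" %in% names(d@params)) d@params[["a"]] else 1
      bb <- if ("b" %in% names(d@params)) d@params[["b"]] else 1
      if (a != 0 && bb != 0)
        push(E(b("source_player"), b("target_player"),
               if (bb > 0) .signOf(a) else .signOf(-a)))
    },
    transformer = ,
    transducer = {
      m <- net@properties[[b("constitutive")]]@value
      push(E(b("force_player_1"), b("force_player_2"), .signOf(m)))
      push(E(b("flow_player_2"), b("flow_player_1"), .signOf(m)))
    },
    transactor = {
      cc <- net@properties[[b("constitutive")]]@value
      if (cc != 0) push(E(b("source_player"), b("target_player"), .signOf(cc)))
    },
    boundary_flow = {
      for (f in b("flow_player")) {
        tg <- b("target_player"); sc <- b("source_player")
        if (length(tg)) push(E(f, tg, "+"))
        if (length(sc)) push(E(f, sc, "-"))
      }
    },
    boundary_force = {
      for (f in b("force_player_high")) push(E(f, b("momentum_player"), "+"))
      for (f in b("force_player_low")) push(E(f, b("momentum_player"), "-"))
    })
  if (length(out)) do.call(rbind, out) else NULL
}

#' Signed influence edges of a validated network
#'
#' Unrolls every dependency into directed, signed edges following the causal
#' orientation the compiler assigns (force differential drives flow through a
#' resistance; stored amount raises capacitive force; flows accumulate into
#' target amounts and drain source amounts; transactor sign follows its
#' coefficient). Feeds the qualitative sign-propagation module.
#'
#' @param net A [ModelNetwork-class] that compiles (causality must be
#'   assignable; otherwise `E_NOT_COMPILED`).
#' @return `data.frame` with columns `from`, `to`, `sign` (`"+"`/`"-"`),
#'   sorted by `from`, `to`, `sign`.
#' @export
influenceEdges <- function(net) {
  tryCatch(assignCausality(net),
           physdepError = function(e)
             physdepStop("E_NOT_COMPILED",
                         paste("causal orientation unavailable:", conditionMessage(e))))
  out <- list()
  for (d in net@dependencies) {
    e <- .depEdges(net, d)
    if (!is.null(e)) out[[length(out) + 1L]] <- e
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(from = character(0), to = character(0), sign = character(0))
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
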