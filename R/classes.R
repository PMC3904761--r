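# S4 classes for model networks: entities, processes, property instances,
# dependency instances, prescribed sources, and the assembled network.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' EntityNode: a physical entity
#'
#' A discrete physical entity (a portion of blood, a cell, a capacitor plate)
#' that bears property instances and may be a proper part of another entity.
#'
#' @slot id Unique identifier.
#' @slot label Human-readable label.
#' @slot domain Biophysical domain id.
#' @slot partOf Parent entity id or `NA` (part-of references form a forest).
#' @export
setClass("EntityNode",
         representation(id = "character", label = "character",
                        domain = "character", partOf = "character"))

#' Construct an EntityNode
#' @param id,label,domain,partOf See [EntityNode-class].
#' @return An `EntityNode`.
#' @export
entityNode <- function(id, domain, label = id, partOf = NA_character_)
  new("EntityNode", id = id, label = label, domain = domain, partOf = partOf)

#' ProcessNode: a physical process
#'
#' Bookkeeping node recording which entities participate in a process; used
#' for RDF `hasParticipant` annotation. Dependencies attach to properties
#' directly, not to processes.
#'
#' @slot id Unique identifier.
#' @slot label Human-readable label.
#' @slot participants Non-empty character vector of entity ids.
#' @export
setClass("ProcessNode",
         representation(id = "character", label = "character",
                        participants = "character"),
         validity = function(object) {
           if (length(object@participants) == 0L) "participants must be non-empty" else TRUE
         })

#' Construct a ProcessNode
#' @param id,label,participants See [ProcessNode-class].
#' @return A `ProcessNode`.
#' @export
processNode <- function(id, participants, label = id)
  new("ProcessNode", id = id, label = label, participants = participants)

#' PropertyInstance: one physical property borne by an entity or process
#'
#' @slot id Unique identifier.
#' @slot propClass Property class id (see [propertyClasses()]).
#' @slot bearer Entity or process id.
#' @slot value Parameter value / initial condition in canonical units, or
#'   `NA` when unset.
#' @export
setClass("PropertyInstance",
         representation(id = "character", propClass = "character",
                        bearer = "character", value = "numeric"))

#' Construct a PropertyInstance
#' @param id,propClass,bearer,value See [PropertyInstance-class].
#' @return A `PropertyInstance`.
#' @export
propertyInstance <- function(id, propClass, bearer, value = NA_real_)
  new("PropertyInstance", id = id, propClass = propClass, bearer = bearer,
      value = as.numeric(value))

#' DependencyInstance: one occurrence of a dependency kind
#'
#' Bindings are stored as an ordered `data.frame` with columns `role` and
#' `property`; binding order matters where a role is multi-valued (e.g. the
#' forward-then-reverse rate constants of a mass-action dependency).
#'
#' @slot id Unique identifier.
#' @slot kind Dependency kind id (see [dependencyCatalog()]).
#' @slot bindings `data.frame(role, property)`.
#' @slot params Named numeric vector of kind-specific parameters
#'   (stoichiometries, spatial coefficients, Michaelis-Menten constants).
#' @export
setClass("DependencyInstance",
         representation(id = "character", kind = "character",
                        bindings = "data.frame", params = "numeric"))

#' Construct a DependencyInstance
#'
#' @param id,kind See [DependencyInstance-class].
#' @param bindings Named list mapping role names to character vectors of
#'   property ids, or a `data.frame(role, property)`.
#' @param params Named numeric vector.
#' @return A `DependencyInstance`.
#' @examples
#' dependencyInstance("dep_r", "resistive",
#'   list(flow_player = "i", force_player_high = "e_src",
#'        force_player_low = "e_cap", constitutive = "R"))
#' @export
dependencyInstance <- function(id, kind, bindings, params = numeric(0)) {
  if (!is.data.frame(bindings)) {
    bindings <- data.frame(
      role = rep(names(bindings), lengths(bindings)),
      property = unlist(bindings, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  rownames(bindings) <- NULL
  new("DependencyInstance", id = id, kind = kind, bindings = bindings,
      params = if (length(params)) stats::setNames(as.numeric(params), names(params)) else numeric(0))
}

# property ids bound to a role, in binding order
.boundTo <- function(dep, role) dep@bindings$property[dep@bindings$role == role]

#' SourceSpec: a prescribed boundary condition
#'
#' Drives a force or flow property with a waveform: `constant` (level),
#' `step` (0 before `tStep`, level after), or `sine`
#' (`level + amplitude * sin(2*pi*t/period + phase)`).
#'
#' @slot property Driven property id (force or flow category).
#' @slot waveform One of `"constant"`, `"step"`, `"sine"`.
#' @slot params Named numeric vector: `level`, `tStep`, `amplitude`,
#'   `period`, `phase` (unused entries ignored).
#' @export
setClass("SourceSpec",
         representation(property = "character", waveform = "character",
                        params = "numeric"))

#' Construct a SourceSpec
#' @param property,waveform See [SourceSpec-class].
#' @param level,tStep,amplitude,period,phase Waveform parameters.
#' @return A `SourceSpec`.
#' @export
sourceSpec <- function(property, waveform = c("constant", "step", "sine"),
                       level = 0, tStep = 0, amplitude = 0, period = 1, phase = 0) {
  waveform <- match.arg(waveform)
  new("SourceSpec", property = property, waveform = waveform,
      params = c(level = level, tStep = tStep, amplitude = amplitude,
                 period = period, phase = phase))
}

.sourceValue <- function(src, t) {
  p <- src@params
  switch(src@waveform,
         constant = rep(p[["level"]], length(t)),
         step = ifelse(t >= p[["tStep"]], p[["level"]], 0),
         sine = p[["level"]] + p[["amplitude"]] * sin(2 * pi * t / p[["period"]] + p[["phase"]]))
}

#' ModelNetwork: the full typed dependency network
#'
#' @slot entities Named list of [EntityNode-class] objects.
#' @slot processes Named list of [ProcessNode-class] objects.
#' @slot properties Named list of [PropertyInstance-class] objects.
#' @slot dependencies Named list of [DependencyInstance-class] objects.
#' @slot sources Named list of [SourceSpec-class] objects (named by driven
#'   property id).
#' @slot metadata List with at least `name`, `description`.
#' @export
setClass("ModelNetwork",
         representation(entities = "list", processes = "list",
                        properties = "list", dependencies = "list",
                        sources = "list", metadata = "list"))

#' Accessors for ModelNetwork collections
#'
#' @param net A [ModelNetwork-class].
#' @return The requested named list (`networkEntities`, `networkProcesses`,
#'   `networkProperties`, `networkDependencies`, `networkSources`) or list
#'   (`networkMetadata`).
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
networkEntities <- function(net) net@entities
#' @rdname network-accessors
#' @export
networkProcesses <- function(net) net@processes
#' @rdname network-accessors
#' @export
networkProperties <- function(net) net@properties
#' @rdname network-accessors
#' @export
networkDependencies <- function(net) net@dependencies
#' @rdname network-accessors
#' @export
networkSources <- function(net) net@sources
#' @rdname network-accessors
#' @export
networkMetadata <- function(net) net@metadata

#' Get or set a property instance's value
#'
#' @param net A [ModelNetwork-class].
#' @param id Property instance id.
#' @param value Replacement numeric value.
#' @return The value (getter) or the modified network (setter).
#' @export
propertyValue <- function(net, id) {
  p <- net@properties[[id]]
  if (is.null(p)) physdepStop("E_UNRESOLVED_REF", sprintf("no property '%s'", id))
  p@value
}

#' @rdname propertyValue
#' @export
`propertyValue<-` <- function(net, id, value) {
  p <- net@properties[[id]]
  if (is.null(p)) physdepStop("E_UNRESOLVED_REF", sprintf("no property '%s'", id))
  p@value <- as.numeric(value)
  net@properties[[id]] <- p
  net
}

# domain of a property instance (via its class)
.propertyDomain <- function(net, pid) .propertyClassById(net@properties[[pid]]@propClass)$domain
.propertyCategory <- function(net, pid) .propertyClassById(net@properties[[pid]]@propClass)$category

setMethod("show", "PropertyInstance", function(object) {
  cat(sprintf("PropertyInstance '%s' <%s> on '%s', value = %s\n",
              object@id, object@propClass, object@bearer,
              ifelse(is.na(object@value), "unset", format(object@value))))
})

setMethod("show", "DependencyInstance", function(object) {
  cat(sprintf("DependencyInstance '%s' (%s)\n", object@id, object@kind))
  for (i in seq_len(nrow(object@bindings)))
    cat(sprintf("  %-20s -> %s\n", object@bindings$role[i], object@bindings$property[i]))
  if (length(object@params))
    cat("  params:", paste(names(object@params), object@params, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ModelNetwork", function(object) {
  cat(sprintf("ModelNetwork '%s': %d entities, %d processes, %d properties, %d dependencies, %d sources\n",
              if (!is.null(object@metadata$name)) object@metadata$name else "<unnamed>",
              length(object@entities), length(object@processes),
              length(object@properties), length(object@dependencies),
              length(object@sources)))
})
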