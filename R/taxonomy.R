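# Property taxonomy: biophysical domains, property categories, property
# classes, canonical units, and the cross-domain analogy map.
#
# The taxonomy follows the system-dynamics (bond-graph) analogy scheme: every
# domain has a generalized force (effort), flow, amount (displacement) and --
# except the chemical domain -- momentum, plus derived constitutive
# proportionalities (resistance, conductance, capacitance, inductance, rate
# constant, modulus, coefficient).

# SI base dimension vector used for symbolic unit checking.
.dimZero <- c(m = 0L, kg = 0L, s = 0L, A = 0L, mol = 0L)

.dimOf <- function(...) {
  v <- .dimZero
  args <- c(...)
  v[names(args)] <- as.integer(args)
  v
}

# Atomic canonical units and their SI base dimensions.
.unitDims <- list(
  "V"     = .dimOf(m = 2, kg = 1, s = -3, A = -1),
  "A"     = .dimOf(A = 1),
  "C"     = .dimOf(s = 1, A = 1),
  "Wb"    = .dimOf(m = 2, kg = 1, s = -2, A = -1),
  "Pa"    = .dimOf(m = -1, kg = 1, s = -2),
  "m^3/s" = .dimOf(m = 3, s = -1),
  "m^3"   = .dimOf(m = 3),
  "Pa·s"  = .dimOf(m = -1, kg = 1, s = -1),
  "J/mol" = .dimOf(m = 2, kg = 1, s = -2, mol = -1),
  "mol/s" = .dimOf(s = -1, mol = 1),
  "mol"   = .dimOf(mol = 1),
  "N"     = .dimOf(m = 1, kg = 1, s = -2),
  "m/s"   = .dimOf(m = 1, s = -1),
  "m"     = .dimOf(m = 1),
  "N·s"   = .dimOf(m = 1, kg = 1, s = -1),
  "1"     = .dimZero
)

# Per-domain units for the four dynamical categories (NA = category absent).
.domainSeed <- list(
  electrical = list(label = "Electrical", force = "V", flow = "A", amount = "C", momentum = "Wb",
                    labels = c(force = "Electrical potential", flow = "Electrical current",
                               amount = "Electrical charge", momentum = "Magnetic flux linkage")),
  fluid      = list(label = "Fluid", force = "Pa", flow = "m^3/s", amount = "m^3", momentum = "Pa·s",
                    labels = c(force = "Fluid pressure", flow = "Fluid flow rate",
                               amount = "Fluid volume", momentum = "Fluid momentum")),
  chemical   = list(label = "Chemical", force = "J/mol", flow = "mol/s", amount = "mol", momentum = NA,
                    labels = c(force = "Chemical potential", flow = "Molar flow rate",
                               amount = "Molar amount")),
  mechanical = list(label = "Mechanical", force = "N", flow = "m/s", amount = "m", momentum = "N·s",
                    labels = c(force = "Mechanical force", flow = "Velocity",
                               amount = "Displacement", momentum = "Mechanical momentum"))
)

# Registry environment: holds the domain table and derived class table so that
# additional domains (thermal, rotational, ...) can be registered at run time
# without touching the law definitions.
.registry <- new.env(parent = emptyenv())

.categoryTable <- data.frame(
  id = c("amount", "momentum", "force", "flow",
         "constitutive.resistance", "constitutive.conductance",
         "constitutive.capacitance", "constitutive.inductance",
         "constitutive.rate_constant", "constitutive.modulus",
         "constitutive.coefficient"),
  group = c("state", "state", "rate", "rate", rep("constitutive", 7L)),
  stringsAsFactors = FALSE
)

# quotient unit string with parentheses around composite operands
.quotientUnit <- function(num, den) {
  wrap <- function(u) if (grepl("[·/]", u)) paste0("(", u, ")") else u
  paste0(wrap(num), "/", wrap(den))
}

.lookupUnitDims <- function(u) {
  extra <- if (exists("unitDims", envir = .registry)) get("unitDims", envir = .registry) else list()
  d <- if (!is.null(extra[[u]])) extra[[u]] else .unitDims[[u]]
  if (is.null(d)) physdepStop("E_BAD_VALUE", sprintf("no dimensions known for unit '%s'", u))
  d
}

.buildDomainRows <- function(domainId, seed) {
  dyn <- c("force", "flow", "amount", "momentum")
  rows <- list()
  units <- character(0)
  dims <- list()
  for (cat in dyn) {
    u <- seed[[cat]]
    if (is.na(u)) next
    units[cat] <- u
    dims[[cat]] <- .lookupUnitDims(u)
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(domainId, ".", cat), domain = domainId, category = cat,
      label = unname(seed$labels[cat]), unit = u, stringsAsFactors = FALSE)
  }
  con <- list(
    "constitutive.resistance"    = c("force", "flow"),
    "constitutive.conductance"   = c("flow", "force"),
    "constitutive.capacitance"   = c("amount", "force"),
    "constitutive.inductance"    = c("momentum", "flow"),
    "constitutive.rate_constant" = c("flow", "amount")
  )
  for (cat in names(con)) {
    nd <- con[[cat]]
    if (!all(nd %in% names(units))) next  # e.g. chemical inductance
    u <- .quotientUnit(units[[nd[1]]], units[[nd[2]]])
    dims[[cat]] <- dims[[nd[1]]] - dims[[nd[2]]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(domainId, ".", cat), domain = domainId, category = cat,
      label = paste(seed$label, sub("constitutive\\.", "", gsub("_", " ", cat))),
      unit = u, stringsAsFactors = FALSE)
  }
  for (cat in c("constitutive.modulus", "constitutive.coefficient")) {
    dims[[cat]] <- .dimZero
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(domainId, ".", cat), domain = domainId, category = cat,
      label = paste(seed$label, sub("constitutive\\.", "", cat)),
      unit = "1", stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(classes = tab, dims = dims)
}

.initRegistry <- function() {
  domains <- data.frame(id = names(.domainSeed),
                        label = vapply(.domainSeed, function(s) s$label, ""),
                        stringsAsFactors = FALSE, row.names = NULL)
  classes <- list(); dims <- list()
  for (d in names(.domainSeed)) {
    built <- .buildDomainRows(d, .domainSeed[[d]])
    classes[[d]] <- built$classes
    dims[[d]] <- built$dims
  }
  assign("domains", domains, envir = .registry)
  assign("classes", do.call(rbind, c(classes, list(make.row.names = FALSE))), envir = .registry)
  assign("dims", dims, envir = .registry)
  invisible(NULL)
}

.ensureRegistry <- function() {
  if (!exists("classes", envir = .registry)) .initRegistry()
  invisible(NULL)
}

#' Registered biophysical domains
#'
#' The four built-in domains are `electrical`, `fluid`, `chemical`, and
#' `mechanical`. Further domains can be added with [registerDomain()].
#'
#' @return A `data.frame` with columns `id` and `label`.
#' @examples
#' biophysicalDomains()
#' @export
biophysicalDomains <- function() {
  .ensureRegistry()
  get("domains", envir = .registry)
}

#' Property categories
#'
#' Categories are partitioned into `state` (amount, momentum), `rate` (force,
#' flow), and `constitutive` (resistance, conductance, capacitance, inductance,
#' rate constant, modulus, coefficient) groups.
#'
#' @return A `data.frame` with columns `id` and `group`.
#' @export
propertyCategories <- function() .categoryTable

.categoryGroup <- function(category) {
  i <- match(category, .categoryTable$id)
  if (is.na(i)) physdepStop("E_NO_SUCH_PROPERTY", sprintf("unknown property category '%s'", category))
  .categoryTable$group[i]
}

#' Registered property classes
#'
#' One class per (domain, category) pair; the chemical domain has no momentum
#' (and hence no inductance) analogue.
#'
#' @return A `data.frame` with columns `id`, `domain`, `category`, `label`,
#'   `unit`.
#' @examples
#' subset(propertyClasses(), domain == "fluid")
#' @export
propertyClasses <- function() {
  .ensureRegistry()
  get("classes", envir = .registry)
}

#' Register an additional biophysical domain
#'
#' Extension hook for domains beyond the built-in four (e.g. thermal,
#' rotational). A full unit row for the dynamical categories must be supplied;
#' constitutive classes and their units are derived by the dimensional rules
#' (resistance = force/flow, capacitance = amount/force, inductance =
#' momentum/flow, rate constant = flow/amount).
#'
#' @param id Domain identifier (unique).
#' @param label Human-readable domain name.
#' @param units Named list with entries `force`, `flow`, `amount` and
#'   optionally `momentum`: canonical unit strings.
#' @param unitDims Named list mapping each new unit string to its SI base
#'   dimension vector (names among m, kg, s, A, mol); may be omitted for units
#'   already known.
#' @param labels Optional named character vector of per-category labels.
#' @return Invisibly, the updated class table.
#' @export
registerDomain <- function(id, label, units, unitDims = list(), labels = NULL) {
  .ensureRegistry()
  domains <- get("domains", envir = .registry)
  if (id %in% domains$id)
    physdepStop("E_DUPLICATE_ID", sprintf("domain '%s' already registered", id))
  extra <- if (exists("unitDims", envir = .registry)) get("unitDims", envir = .registry) else list()
  for (u in names(unitDims)) extra[[u]] <- .dimOf(unitDims[[u]])
  assign("unitDims", extra, envir = .registry)
  if (is.null(labels))
    labels <- stats::setNames(paste(label, names(units)), names(units))
  seed <- list(label = label, force = units$force, flow = units$flow,
               amount = units$amount,
               momentum = if (is.null(units$momentum)) NA else units$momentum,
               labels = labels)
  for (u in unlist(units)) .lookupUnitDims(u)
  built <- .buildDomainRows(id, seed)
  assign("domains", rbind(domains, data.frame(id = id, label = label)), envir = .registry)
  assign("classes", rbind(get("classes", envir = .registry), built$classes), envir = .registry)
  dims <- get("dims", envir = .registry); dims[[id]] <- built$dims
  assign("dims", dims, envir = .registry)
  invisible(get("classes", envir = .registry))
}

.propertyClassRow <- function(domain, category) {
  tab <- propertyClasses()
  i <- which(tab$domain == domain & tab$category == category)
  if (length(i) != 1L)
    physdepStop("E_NO_SUCH_PROPERTY",
                sprintf("no property class for domain '%s', category '%s'", domain, category))
  tab[i, , drop = FALSE]
}

.propertyClassById <- function(classId) {
  tab <- propertyClasses()
  i <- match(classId, tab$id)
  if (is.na(i))
    physdepStop("E_NO_SUCH_PROPERTY", sprintf("unknown property class '%s'", classId))
  tab[i, , drop = FALSE]
}

#' Canonical unit of a (domain, category) pair
#'
#' Dynamical units come from a fixed table (V, A, C, Wb; Pa, m^3/s, m^3, Pa·s;
#' J/mol, mol/s, mol; N, m/s, m, N·s); constitutive units are the quotients
#' mandated by the defining relations.
#'
#' @param domain Domain id.
#' @param category Category id.
#' @return Unit string.
#' @examples
#' canonicalUnit("electrical", "flow")            # "A"
#' canonicalUnit("mechanical", "constitutive.inductance")
#' @export
canonicalUnit <- function(domain, category) .propertyClassRow(domain, category)$unit

#' SI base dimensions of a canonical unit
#'
#' Reduces the canonical unit of a (domain, category) pair to SI base-dimension
#' exponents, enabling symbolic checks such as mechanical inductance
#' `N·s/(m/s)` reducing to `kg`.
#'
#' @inheritParams canonicalUnit
#' @return Named integer vector over `m, kg, s, A, mol`.
#' @export
unitDimensions <- function(domain, category) {
  .ensureRegistry()
  .propertyClassRow(domain, category)  # existence check
  get("dims", envir = .registry)[[domain]][[category]]
}

#' Cross-domain analog of a property class
#'
#' Maps a dynamical (state or rate) property class onto the class with the same
#' category in another domain, e.g. electrical potential onto fluid pressure.
#' The map is a bijection between any two domains restricted to the categories
#' both possess.
#'
#' @param classId Property class id (e.g. `"electrical.force"`) or one-row
#'   class `data.frame` from [propertyClasses()].
#' @param target Target domain id.
#' @return One-row `data.frame` of the analog class.
#' @examples
#' analogOf("electrical.force", "fluid")$label    # Fluid pressure
#' @export
analogOf <- function(classId, target) {
  if (is.data.frame(classId)) classId <- classId$id
  row <- .propertyClassById(classId)
  if (!.categoryGroup(row$category) %in% c("state", "rate"))
    physdepStop("E_NO_SUCH_PROPERTY",
                sprintf("'%s' is constitutive; analogs are defined for state/rate classes", classId))
  .propertyClassRow(target, row$category)
}

#' Export the full taxonomy as a machine-readable document
#'
#' Serializes domains, categories, property classes, units, the analogy map,
#' and the dependency-kind catalogue (role signatures) to a single YAML
#' document, usable as documentation and as the seed for the RDF exporter's
#' IRI map.
#'
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to `path`.
#' @export
writeTaxonomyYAML <- function(path = NULL) {
  cat_ <- propertyCategories()
  cls <- propertyClasses()
  kinds <- dependencyCatalog()
  doc <- list(
    format = "physdep-taxonomy",
    version = "1.0",
    domains = lapply(seq_len(nrow(biophysicalDomains())), function(i)
      as.list(biophysicalDomains()[i, ])),
    categories = lapply(seq_len(nrow(cat_)), function(i) as.list(cat_[i, ])),
    property_classes = lapply(seq_len(nrow(cls)), function(i) as.list(cls[i, ])),
    dependency_kinds = lapply(kinds, function(k) list(
      id = k$id, label = k$label, domain_rule = k$domainRule,
      roles = lapply(k$roles, function(r) list(
        categories = r$categories, min = r$min,
        max = if (is.finite(r$max)) r$max else "unbounded")),
      outputs = k$outputs))
  )
  txt <- yaml::as.yaml(doc, precision = 17L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
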