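# Model document I/O: the versioned YAML model dialect (native authoring
# format) and the RDF 1.1 Turtle annotation export.

.MODEL_FORMAT <- "physdep-model"
.MODEL_VERSION <- "1.0"

#' Read a model document
#'
#' Parses the YAML model dialect (sections `entities`, `processes?`,
#' `properties`, `dependencies`, `sources?`, `metadata`) and assembles a
#' [ModelNetwork-class]. Unparseable files raise `E_PARSE`; wrong
#' format/version or unknown dependency kinds raise `E_SCHEMA`; dangling ids
#' raise `E_UNRESOLVED_REF`.
#'
#' @param path File path.
#' @return A [ModelNetwork-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) physdepStop("E_PARSE", sprintf("no such file: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) physdepStop("E_PARSE", conditionMessage(e)))
  if (!is.list(doc) || !identical(doc$format, .MODEL_FORMAT))
    physdepStop("E_SCHEMA", sprintf("%s: not a %s document", path, .MODEL_FORMAT))
  if (!identical(as.character(doc$version), .MODEL_VERSION))
    physdepStop("E_SCHEMA", sprintf("%s: unsupported version '%s' (expected %s)",
                                    path, doc$version, .MODEL_VERSION), version = doc$version)
  for (d in doc$dependencies)
    if (is.null(.kindList[[d$kind]]))
      physdepStop("E_SCHEMA", sprintf("%s: unknown dependency kind '%s' (dependency '%s')",
                                      path, d$kind, d$id))
  assembleNetwork(doc)
}

# canonical plain-list form of a network (deterministic key order)
.networkDocument <- function(net) {
  compact <- function(x) x[!vapply(x, function(v) is.null(v) || (length(v) == 1L && is.na(v)), TRUE)]
  doc <- list(
    format = .MODEL_FORMAT,
    version = .MODEL_VERSION,
    metadata = list(name = net@metadata$name, description = net@metadata$description),
    entities = lapply(unname(net@entities), function(e)
      compact(list(id = e@id, label = e@label, domain = e@domain, part_of = e@partOf))),
    processes = lapply(unname(net@processes), function(p)
      list(id = p@id, label = p@label, participants = as.list(p@participants))),
    properties = lapply(unname(net@properties), function(p)
      compact(list(id = p@id, class = p@propClass, bearer = p@bearer,
                   unit = .propertyClassById(p@propClass)$unit, value = p@value))),
    dependencies = lapply(unname(net@dependencies), function(d) {
      out <- list(id = d@id, kind = d@kind,
                  bindings = lapply(seq_len(nrow(d@bindings)), function(i)
                    list(role = d@bindings$role[i], property = d@bindings$property[i])))
      if (length(d@params)) out$params <- as.list(d@params)
      out
    }),
    sources = lapply(unname(net@sources), function(s) {
      p <- as.list(s@params)
      keep <- switch(s@waveform, constant = "level", step = c("level", "tStep"),
                     sine = c("level", "amplitude", "period", "phase"))
      c(list(property = s@property, waveform = s@waveform),
        stats::setNames(p[keep], sub("tStep", "t_step", keep)))
    }))
  if (!length(doc$processes)) doc$processes <- NULL
  if (!length(doc$sources)) doc$sources <- NULL
  doc
}

#' Write a model document
#'
#' Deterministic serialization of the network in the YAML model dialect:
#' canonical key order, canonical units written explicitly, format version
#' stamped, numbers at full double precision. Two writes of the same network
#' are byte-identical, and `readModel(writeModel(net))` reproduces the network
#' id-for-id and value-for-value.
#'
#' @param net A [ModelNetwork-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeModel <- function(net, path) {
  txt <- yaml::as.yaml(.networkDocument(net), precision = 17L, indent.mapping.sequence = TRUE)
  writeLines(txt, path, sep = "")
  invisible(path)
}

# role name -> RDF role predicate (sub-properties of hasPropertyPlayer)
.rolePredicate <- function(role) {
  if (grepl("^force_player", role)) return("hasForcePlayer")
  if (grepl("^flow_player", role)) return("hasFlowPlayer")
  switch(role,
         amount_player = "hasAmountPlayer",
         momentum_player = "hasMomentumPlayer",
         whole_player = "hasWholePlayer",
         part_player = "hasPartPlayer",
         source_player = "hasSourcePlayer",
         target_player = "hasTargetPlayer",
         constitutive = "hasConstitutiveProportionality",
         physdepStop("E_NO_IRI", sprintf("no role predicate for role '%s'", role)))
}

#' Default IRI map for RDF export
#'
#' Maps every taxonomy id (property classes, dependency kinds, role names,
#' structural predicates) to a deliberately non-resolvable placeholder
#' namespace (`urn:x-physdep:`), so placeholder IRIs can never be confused
#' with real published ontology IRIs; supply your own map to target one.
#'
#' @return Named character vector id -> IRI.
#' @export
defaultIriMap <- function() {
  cls <- propertyClasses()$id
  kinds <- names(dependencyCatalog())
  roles <- unique(unlist(lapply(dependencyCatalog(), function(k) names(k$roles))))
  preds <- unique(c(vapply(roles, .rolePredicate, ""),
                    "hasProperty", "hasParticipant", "partOf"))
  c(stats::setNames(paste0("urn:x-physdep:class#", cls), cls),
    stats::setNames(paste0("urn:x-physdep:kind#", kinds), kinds),
    stats::setNames(paste0("urn:x-physdep:relation#", preds), preds),
    PhysicalEntity = "urn:x-physdep:class#PhysicalEntity",
    PhysicalProcess = "urn:x-physdep:class#PhysicalProcess")
}

.iri <- function(map, id) {
  v <- map[id]
  if (any(is.na(v))) physdepStop("E_NO_IRI", sprintf("IRI map lacks id '%s'", id[is.na(v)][1]), id = id[is.na(v)][1])
  unname(v)
}

#' Export a network as RDF Turtle annotations
#'
#' Emits, in deterministic order: each entity/process typed and linked to its
#' properties via `hasProperty` (processes also via `hasParticipant` to their
#' participants); each property instance typed by its property-class IRI;
#' each dependency instance typed by its kind IRI with one role-predicate
#' triple per binding (`hasFlowPlayer`, `hasForcePlayer`,
#' `hasConstitutiveProportionality`, ...).
#'
#' @param net A valid [ModelNetwork-class].
#' @param path Optional output file; when `NULL` the Turtle text is returned.
#' @param iriMap Named character vector taxonomy-id -> IRI (see
#'   [defaultIriMap()]); `E_NO_IRI` if an id is missing.
#' @return Turtle text (invisibly when written to `path`).
#' @export
exportRDF <- function(net, path = NULL, iriMap = defaultIriMap()) {
  esc <- function(s) gsub('"', '\\\\"', s)
  node <- function(id) sprintf("<urn:x-physdep:model/%s#%s>", net@metadata$name, id)
  lines <- character(0)
  emit <- function(s, p, o) lines[[length(lines) + 1L]] <<- sprintf("%s %s %s .", s, p, o)

  for (id in sort(names(net@entities))) {
    e <- net@entities[[id]]
    emit(node(id), "a", sprintf("<%s>", .iri(iriMap, "PhysicalEntity")))
    emit(node(id), "<http://www.w3.org/2000/01/rdf-schema#label>", sprintf('"%s"', esc(e@label)))
    if (!is.na(e@partOf))
      emit(node(id), sprintf("<%s>", .iri(iriMap, "partOf")), node(e@partOf))
  }
  for (id in sort(names(net@processes))) {
    p <- net@processes[[id]]
    emit(node(id), "a", sprintf("<%s>", .iri(iriMap, "PhysicalProcess")))
    emit(node(id), "<http://www.w3.org/2000/01/rdf-schema#label>", sprintf('"%s"', esc(p@label)))
    for (pt in p@participants)
      emit(node(id), sprintf("<%s>", .iri(iriMap, "hasParticipant")), node(pt))
  }
  for (id in sort(names(net@properties))) {
    pr <- net@properties[[id]]
    emit(node(id), "a", sprintf("<%s>", .iri(iriMap, pr@propClass)))
    emit(node(pr@bearer), sprintf("<%s>", .iri(iriMap, "hasProperty")), node(id))
  }
  for (id in sort(names(net@dependencies))) {
    d <- net@dependencies[[id]]
    emit(node(id), "a", sprintf("<%s>", .iri(iriMap, d@kind)))
    for (i in seq_len(nrow(d@bindings)))
      emit(node(id), sprintf("<%s>", .iri(iriMap, .rolePredicate(d@bindings$role[i]))),
           node(d@bindings$property[i]))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
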