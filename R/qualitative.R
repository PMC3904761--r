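# Qualitative up/down perturbation reasoning: propagate perturbation signs
# over the influence graph without numeric solving, and cross-check the
# predictions against numeric steady-state differences.

# sign algebra over {"+", "-", "0", "?"}
signMul <- function(a, b) {
  if (a == "0" || b == "0") return("0")
  if (a == "?" || b == "?") return("?")
  if (a == b) "+" else "-"
}
signAdd <- function(a, b) {
  if (a == "0") return(b)
  if (b == "0") return(a)
  if (a == "?" || b == "?") return("?")
  if (a == b) a else "?"
}
signNeg <- function(a) switch(a, "+" = "-", "-" = "+", a)

#' Influence graph of a network
#'
#' Nodes are the dynamical property ids; edges are the signed influences from
#' [influenceEdges()].
#'
#' @param net A compilable [ModelNetwork-class].
#' @return List with `nodes` (character) and `edges`
#'   (`data.frame(from, to, sign)`).
#' @export
influenceGraph <- function(net) {
  edges <- influenceEdges(net)
  nodes <- sort(Filter(function(pid) .categoryGroup(.propertyCategory(net, pid)) != "constitutive",
                       names(net@properties)))
  list(nodes = nodes, edges = edges)
}

#' Propagate a perturbation sign over the influence graph
#'
#' The perturbed node is assigned `+` (up) or `-` (down); every other node
#' receives the sign-sum, over all simple paths from the perturbed node, of
#' the product of edge signs along each path (`?` absorbs conflicting
#' contributions). Unreached nodes get `0`. Deterministic and independent of
#' node iteration order.
#'
#' @param graph An influence graph from [influenceGraph()] (a
#'   [ModelNetwork-class] is also accepted).
#' @param perturbed Property id to perturb.
#' @param direction `"up"` or `"down"`.
#' @return Named character vector over all nodes with values in
#'   `{"+", "-", "0", "?"}`.
#' @examples
#' net <- makeFixture("baroreflex_toy")
#' propagateSign(influenceGraph(net), "baro_pressure", "up")
#' @export
propagateSign <- function(graph, perturbed, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is(graph, "ModelNetwork")) graph <- influenceGraph(graph)
  if (!perturbed %in% graph$nodes)
    physdepStop("E_UNRESOLVED_REF", sprintf("unknown property '%s'", perturbed))
  adj <- split(graph$edges[c("to", "sign")], graph$edges$from)
  acc <- stats::setNames(rep("0", length(graph$nodes)), graph$nodes)
  root <- if (direction == "up") "+" else "-"
  acc[perturbed] <- root

  walk <- function(node, sign, visited) {
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible(NULL))
    for (i in seq_len(nrow(nb))) {
      to <- nb$to[i]
      if (to %in% visited) next
      s2 <- signMul(sign, nb$sign[i])
      if (to != perturbed) acc[to] <<- signAdd(acc[to], s2)
      walk(to, s2, c(visited, to))
    }
  }
  walk(perturbed, root, perturbed)
  acc
}

#' Cross-check qualitative signs against a numeric steady-state oracle
#'
#' Computes numeric steady states at baseline and with the perturbed source's
#' level scaled by `1 + relStep`, classifies each property's change as
#' `+`/`-`/`0` (tolerance `1e-9 * max(1, |baseline|)`), and compares with the
#' propagated qualitative signs. Agreement classes: `agree` (signs equal),
#' `conservative` (`?`, or a qualitative `+`/`-` whose steady-state numeric
#' change is exactly 0 -- a transient influence that cancels at equilibrium,
#' e.g. the RC charging current), `missed` (qualitative 0, numeric nonzero),
#' `contradict` (strict opposite signs -- a soundness failure).
#'
#' @param net A compilable [ModelNetwork-class] with constant sources.
#' @param perturbed Id of a source-driven property.
#' @param relStep Relative perturbation of the source level (default 0.01).
#' @param tMax,dt,tol Passed to [steadyState()].
#' @return `data.frame(property, qualitative, numeric, agreement)`, ordered by
#'   property id.
#' @export
checkAgainstNumeric <- function(net, perturbed, relStep = 0.01,
                                tMax = 200, dt = 0.01, tol = 1e-12) {
  if (!perturbed %in% names(net@sources))
    physdepStop("E_BAD_SOURCE",
                sprintf("'%s' is not a source property; qualitative perturbations target sources", perturbed))
  base <- steadyState(compileNetwork(net), tMax = tMax, dt = dt, tol = tol)
  net2 <- net
  s <- net2@sources[[perturbed]]
  s@params[["level"]] <- s@params[["level"]] * (1 + relStep)
  s@params[["amplitude"]] <- s@params[["amplitude"]] * (1 + relStep)
  net2@sources[[perturbed]] <- s
  pert <- steadyState(compileNetwork(net2), tMax = tMax, dt = dt, tol = tol)

  graph <- influenceGraph(net)
  qual <- propagateSign(graph, perturbed, "up")
  numSign <- vapply(graph$nodes, function(pid) {
    d <- pert$values[[pid]] - base$values[[pid]]
    if (abs(d) <= 1e-9 * max(1, abs(base$values[[pid]]))) "0" else if (d > 0) "+" else "-"
  }, "")
  agreement <- vapply(graph$nodes, function(pid) {
    q <- qual[[pid]]; nu <- numSign[[pid]]
    if (q == nu) "agree"
    else if (q == "?") "conservative"
    else if (nu == "0" && q %in% c("+", "-")) "conservative"
    else if (q == "0" && nu != "0") "missed"
    else "contradict"
  }, "")
  data.frame(property = graph$nodes, qualitative = unname(qual[graph$nodes]),
             numeric = unname(numSign), agreement = unname(agreement),
             stringsAsFactors = FALSE)
}

#' Write a perturbation agreement report as TSV
#'
#' @param report Output of [checkAgainstNumeric()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePerturbationReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
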