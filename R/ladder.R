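#' Assemble a relative-acidity measurement graph
#'
#' The "ladder" of a relative-acidity study is a graph: nodes are acids,
#' edges are directly measured \eqn{\Delta pK_a} values between pairs.
#' Anchor nodes carry a previously established absolute pKa that pins
#' the gauge of the least-squares solution; the remaining nodes belong
#' to reliability tiers (`backbone`, `secondary`, `tertiary`) that are
#' solved in successive minimization steps.
#'
#' @param nodes Data frame with columns `id` (unique), `name`
#'   (optional), `tier` (one of `anchor`, `backbone`, `secondary`,
#'   `tertiary`) and `fixed_pka` (required and finite for anchors,
#'   `NA` otherwise).
#' @param edges Data frame with columns `acid_1`, `acid_2` (node ids,
#'   distinct per edge), `delta_pka` (`= pKa(acid_2) - pKa(acid_1)`),
#'   and optionally `reliability` (`high`/`medium`/`low`), `included`
#'   (logical, default `TRUE`) and `reason` (for excluded edges).
#' @return An object of class `measurement_graph`.
#' @seealso [solve_ladder()], [tiered_solve()], [validate_graph()]
#' @export
measurement_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "tier") %in% names(nodes)))
    stop("nodes need columns id and tier", call. = FALSE)
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  if (!"fixed_pka" %in% names(nodes)) nodes$fixed_pka <- NA_real_
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique", call. = FALSE)
  ok_tiers <- c("anchor", "backbone", "secondary", "tertiary")
  if (!all(nodes$tier %in% ok_tiers))
    stop("tier must be one of: ", paste(ok_tiers, collapse = ", "),
         call. = FALSE)
  anc <- nodes$tier == "anchor"
  if (any(anc & !is.finite(nodes$fixed_pka)))
    stop("anchor nodes must carry a finite fixed_pka", call. = FALSE)
  if (!all(c("acid_1", "acid_2", "delta_pka") %in% names(edges)))
    stop("edges need columns acid_1, acid_2, delta_pka", call. = FALSE)
  edges$acid_1 <- as.character(edges$acid_1)
  edges$acid_2 <- as.character(edges$acid_2)
  if (!"reliability" %in% names(edges)) edges$reliability <- "high"
  if (!"included" %in% names(edges)) edges$included <- TRUE
  if (!"reason" %in% names(edges)) edges$reason <- NA_character_
  edges$included <- as.logical(edges$included)
  bad <- !(edges$acid_1 %in% nodes$id) | !(edges$acid_2 %in% nodes$id)
  if (any(bad))
    stop("edge endpoints missing from node table: ",
         paste(unique(c(edges$acid_1[bad], edges$acid_2[bad])
                      [!(c(edges$acid_1[bad], edges$acid_2[bad]) %in%
                           nodes$id)]), collapse = ", "), call. = FALSE)
  if (any(edges$acid_1 == edges$acid_2))
    stop("self-edges (acid_1 == acid_2) are not allowed", call. = FALSE)
  if (!all(is.finite(edges$delta_pka)))
    stop("delta_pka values must be finite", call. = FALSE)
  # deterministic node ordering for reproducible linear algebra
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "measurement_graph")
}

#' @export
print.measurement_graph <- function(x, ...) {
  cat(sprintf(
    "<measurement_graph> %d acids (%d anchored), %d measurements (%d included)\n",
    nrow(x$nodes), sum(x$nodes$tier == "anchor"), nrow(x$edges),
    sum(x$edges$included)))
  invisible(x)
}

tier_level <- function(tier) {
  match(tier, c("anchor", "backbone", "secondary", "tertiary")) - 1L
}

# igraph over the included edges, keeping isolated nodes
graph_components <- function(graph, edges = graph$edges[graph$edges$included, ]) {
  g <- igraph::graph_from_data_frame(
    edges[, c("acid_1", "acid_2"), drop = FALSE], directed = FALSE,
    vertices = graph$nodes$id)
  comp <- igraph::components(g)$membership
  comp[graph$nodes$id]
}

#' Diagnose a measurement graph before solving
#'
#' Emits the checks a careful relative-acidity study applies before the
#' least-squares assignment: every acid should be measured against at
#' least three distinct partners; direct \eqn{\Delta pK_a}
#' determinations with magnitude above `reliability_threshold`
#' (default 1.5) are flagged as less accurate because the window where
#' both acids are partially dissociated becomes narrow or empty; and a
#' connected component without any fixed-pKa node cannot be assigned
#' absolute values at all.
#'
#' @param graph A [measurement_graph].
#' @param reliability_threshold Magnitude above which an edge is
#'   flagged.
#' @return A data frame of diagnostics with columns `level`
#'   (`"error"`, `"warning"` or `"flag"`), `subject` and `message`.
#'   Zero rows means a clean graph.
#' @export
validate_graph <- function(graph, reliability_threshold = 1.5) {
  stopifnot(inherits(graph, "measurement_graph"))
  out <- list()
  ed <- graph$edges[graph$edges$included, , drop = FALSE]
  # partner counts over included edges
  for (id in graph$nodes$id) {
    partners <- unique(c(ed$acid_2[ed$acid_1 == id],
                         ed$acid_1[ed$acid_2 == id]))
    if (length(partners) < 3L)
      out[[length(out) + 1L]] <- data.frame(
        level = "warning", subject = id,
        message = sprintf(
          "acid %s measured against only %d distinct partner(s); at least 3 recommended",
          id, length(partners)))
  }
  big <- which(abs(graph$edges$delta_pka) > reliability_threshold &
                 graph$edges$included)
  for (i in big)
    out[[length(out) + 1L]] <- data.frame(
      level = "flag",
      subject = paste(graph$edges$acid_1[i], graph$edges$acid_2[i],
                      sep = " / "),
      message = sprintf(
        "|delta pKa| = %.2f exceeds %.2f; low-reliability determination",
        abs(graph$edges$delta_pka[i]), reliability_threshold))
  comp <- graph_components(graph)
  fixed <- is.finite(graph$nodes$fixed_pka)
  for (k in unique(comp)) {
    ids <- graph$nodes$id[comp == k]
    if (!any(fixed[comp == k]))
      out[[length(out) + 1L]] <- data.frame(
        level = "error", subject = paste(ids, collapse = ", "),
        message = "connected component has no node with a fixed pKa; absolute values unassignable")
  }
  if (!length(out))
    return(data.frame(level = character(), subject = character(),
                      message = character()))
  do.call(rbind, out)
}

#' Exclude measurement edges with recorded reasons
#'
#' Reproduces the study practice of removing individual relative-acidity
#' determinations judged unreliable (e.g. very large \eqn{\Delta pK_a}
#' values): the edges stay in the graph with `included = FALSE` and the
#' reason retained, and the solvers ignore them.
#'
#' @param graph A [measurement_graph].
#' @param exclusions Data frame with columns `acid_1`, `acid_2` and
#'   optionally `reason`.  Orientation is ignored; all measurements
#'   between the named pair are excluded.
#' @return The modified [measurement_graph].
#' @export
exclude_edges <- function(graph, exclusions) {
  stopifnot(inherits(graph, "measurement_graph"))
  exclusions <- as.data.frame(exclusions, stringsAsFactors = FALSE)
  if (!nrow(exclusions)) return(graph)
  if (!all(c("acid_1", "acid_2") %in% names(exclusions)))
    stop("exclusions need columns acid_1 and acid_2", call. = FALSE)
  if (!"reason" %in% names(exclusions)) exclusions$reason <- "excluded"
  for (i in seq_len(nrow(exclusions))) {
    a <- as.character(exclusions$acid_1[i])
    b <- as.character(exclusions$acid_2[i])
    hit <- (graph$edges$acid_1 == a & graph$edges$acid_2 == b) |
      (graph$edges$acid_1 == b & graph$edges$acid_2 == a)
    if (!any(hit))
      stop(sprintf("no measurement between %s and %s to exclude", a, b),
           call. = FALSE)
    graph$edges$included[hit] <- FALSE
    graph$edges$reason[hit] <- as.character(exclusions$reason[i])
  }
  graph
}

#' Assign absolute pKa values by anchored least squares
#'
#' Minimizes the sum of squared differences between every included
#' measured \eqn{\Delta pK_a} and the difference of the assigned
#' absolute values,
#' \deqn{SSD = \sum_{m=1}^{n_m} \left(\Delta pK_a^{(m)} -
#'   \left[pK_a(HA_2^{(m)}) - pK_a(HA_1^{(m)})\right]\right)^2,}
#' holding the frozen (anchor) values exactly constant.  The minimizer
#' is obtained from the linear least-squares problem on the edge
#' incidence design via QR; it is unique whenever every connected
#' component contains a frozen node.  Edges whose endpoints are both
#' frozen carry no information for the step and are left out of the fit
#' and of `n_m`.
#'
#' @param graph A [measurement_graph].
#' @param frozen Named numeric vector of node values held constant.
#'   Defaults to all nodes with a finite `fixed_pka`.
#' @return A `ladder_solution`: list with `assigned` (named pKa vector
#'   over all nodes in the step), `residuals` (data frame per used
#'   edge), `ssd`, `n_m`, `n_c` (free-node count), and the consistency
#'   standard deviation `s` (`NA` when `n_m <= n_c`).
#' @examples
#' g <- measurement_graph(
#'   nodes = data.frame(id = c("A", "B"), tier = c("anchor", "backbone"),
#'                      fixed_pka = c(10, NA)),
#'   edges = data.frame(acid_1 = "A", acid_2 = "B", delta_pka = 1.5))
#' solve_ladder(g)$assigned
#' @export
solve_ladder <- function(graph, frozen = NULL) {
  stopifnot(inherits(graph, "measurement_graph"))
  nodes <- graph$nodes
  if (is.null(frozen)) {
    fx <- is.finite(nodes$fixed_pka)
    frozen <- stats::setNames(nodes$fixed_pka[fx], nodes$id[fx])
  }
  if (!length(frozen) || is.null(names(frozen)))
    stop("frozen must be a named numeric vector of fixed pKa values",
         call. = FALSE)
  if (!all(names(frozen) %in% nodes$id))
    stop("frozen names not in graph: ",
         paste(setdiff(names(frozen), nodes$id), collapse = ", "),
         call. = FALSE)
  free <- sort(setdiff(nodes$id, names(frozen)))
  ed <- graph$edges[graph$edges$included, , drop = FALSE]
  # every free node must reach a frozen node through included edges
  comp <- graph_components(graph, ed)
  for (k in unique(comp)) {
    ids <- names(comp)[comp == k]
    if (any(ids %in% free) && !any(ids %in% names(frozen)))
      stop("unsolvable component without a frozen node: ",
           paste(sort(ids), collapse = ", "), call. = FALSE)
  }
  # drop edges carrying no free node
  use <- ed$acid_1 %in% free | ed$acid_2 %in% free
  ed <- ed[use, , drop = FALSE]
  n_c <- length(free)
  n_m <- nrow(ed)
  if (n_c > 0L) {
    if (!n_m)
      stop("no included measurements involve the free nodes", call. = FALSE)
    X <- matrix(0, n_m, n_c, dimnames = list(NULL, free))
    y <- ed$delta_pka
    for (i in seq_len(n_m)) {
      a1 <- ed$acid_1[i]; a2 <- ed$acid_2[i]
      # delta = p(a2) - p(a1): frozen endpoints move to the response side
      if (a2 %in% free) X[i, a2] <- X[i, a2] + 1 else y[i] <- y[i] - frozen[a2]
      if (a1 %in% free) X[i, a1] <- X[i, a1] - 1 else y[i] <- y[i] + frozen[a1]
    }
    qr_x <- qr(X)
    if (qr_x$rank < n_c)
      stop("singular least-squares system; free nodes underdetermined",
           call. = FALSE)
    beta <- qr.coef(qr_x, y)
  } else {
    beta <- numeric(0)
  }
  assigned <- c(frozen, beta)
  assigned <- assigned[sort(names(assigned))]
  resid <- if (n_m) ed$delta_pka -
    (assigned[ed$acid_2] - assigned[ed$acid_1]) else numeric(0)
  ssd <- sum(resid^2)
  structure(list(
    assigned = assigned,
    residuals = data.frame(acid_1 = ed$acid_1, acid_2 = ed$acid_2,
                           delta_pka = ed$delta_pka,
                           residual = as.numeric(resid)),
    ssd = ssd, n_m = n_m, n_c = n_c,
    s = if (n_m > n_c) sqrt(ssd / (n_m - n_c)) else NA_real_,
    steps = NULL), class = "ladder_solution")
}

#' Consistency standard deviation of a ladder solution
#'
#' \deqn{s = \sqrt{SSD / (n_m - n_c)}}
#' where \eqn{n_m} is the number of measurement series used and
#' \eqn{n_c} the number of acids whose absolute pKa was assigned in the
#' fit.  `s` is not the uncertainty of an individual pKa value; it is a
#' global quality estimate of the scale, loosely interpretable as the
#' average standard uncertainty of the values with respect to the
#' scale.
#'
#' @param solution A `ladder_solution` (or any list with `ssd`, `n_m`,
#'   `n_c`).
#' @return `s` in pKa units.
#' @export
consistency_sd <- function(solution) {
  if (!all(c("ssd", "n_m", "n_c") %in% names(solution)))
    stop("solution must carry ssd, n_m and n_c", call. = FALSE)
  if (solution$n_m <= solution$n_c)
    stop("consistency standard deviation undefined: n_m <= n_c",
         call. = FALSE)
  sqrt(solution$ssd / (solution$n_m - solution$n_c))
}

#' @export
print.ladder_solution <- function(x, digits = 2, ...) {
  cat(sprintf(
    "<ladder_solution> %d acids assigned; n_m = %d, n_c = %d, SSD = %.4g, s = %s\n",
    length(x$assigned), x$n_m, x$n_c, x$ssd,
    if (is.na(x$s)) "NA" else sprintf("%.3f", x$s)))
  if (!is.null(x$steps))
    for (st in x$steps)
      cat(sprintf("  step %-9s n_m = %3d, n_c = %3d, s = %s\n", st$tier,
                  st$n_m, st$n_c,
                  if (is.na(st$s)) "NA" else sprintf("%.3f", st$s)))
  print(round(x$assigned, digits))
  invisible(x)
}

#' Tiered (multi-step) ladder assignment
#'
#' Reproduces the sequential minimization used for mixed-reliability
#' measurement networks.  Step 1 assigns the backbone acids using only
#' measurements among backbone and anchor acids; step 2 freezes those
#' and assigns the secondary acids from measurements that involve at
#' least one secondary acid (against already-fixed or secondary
#' partners); step 3 freezes everything so far and assigns the tertiary
#' acids.  Each step reports its own consistency standard deviation, so
#' the quality of each reliability class is visible separately.
#'
#' @param graph A [measurement_graph].
#' @return A `ladder_solution` whose `assigned` covers every node,
#'   with per-step entries under `steps` (tier, `n_m`, `n_c`, `ssd`,
#'   `s`) and pooled `ssd`/`n_m`/`n_c`/`s` over all steps.
#' @export
tiered_solve <- function(graph) {
  stopifnot(inherits(graph, "measurement_graph"))
  nodes <- graph$nodes
  lev <- tier_level(nodes$tier)
  fx <- nodes$tier == "anchor"
  frozen <- stats::setNames(nodes$fixed_pka[fx], nodes$id[fx])
  if (!length(frozen))
    stop("tiered solve needs at least one anchor node", call. = FALSE)
  steps <- list()
  residuals <- list()
  for (t in 1:3) {
    tier_name <- c("backbone", "secondary", "tertiary")[t]
    in_tier <- nodes$id[lev == t]
    if (!length(in_tier)) next
    keep_nodes <- nodes$id[lev <= t]
    e <- graph$edges
    l1 <- lev[match(e$acid_1, nodes$id)]
    l2 <- lev[match(e$acid_2, nodes$id)]
    step_edges <- e[e$included & pmax(l1, l2) == t & pmin(l1, l2) <= t, ,
                    drop = FALSE]
    sub <- measurement_graph(nodes[nodes$id %in% keep_nodes, , drop = FALSE],
                             step_edges)
    sol <- solve_ladder(sub, frozen = frozen)
    new_ids <- setdiff(names(sol$assigned), names(frozen))
    frozen <- c(frozen, sol$assigned[new_ids])
    steps[[length(steps) + 1L]] <- list(tier = tier_name, n_m = sol$n_m,
                                        n_c = sol$n_c, ssd = sol$ssd,
                                        s = sol$s)
    residuals[[length(residuals) + 1L]] <- sol$residuals
  }
  if (!length(steps))
    stop("graph has no non-anchor nodes to solve", call. = FALSE)
  assigned <- frozen[sort(names(frozen))]
  ssd <- sum(vapply(steps, `[[`, numeric(1), "ssd"))
  n_m <- sum(vapply(steps, `[[`, numeric(1), "n_m"))
  n_c <- sum(vapply(steps, `[[`, numeric(1), "n_c"))
  structure(list(
    assigned = assigned,
    residuals = do.call(rbind, residuals),
    ssd = ssd, n_m = n_m, n_c = n_c,
    s = if (n_m > n_c) sqrt(ssd / (n_m - n_c)) else NA_real_,
    steps = steps), class = "ladder_solution")
}
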