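# Experimental designs over batches and cell types, and the batch-graph
# identifiability check.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

.designViolation <- function(...) {
  stop(structure(class = c("designViolation", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Build an experimental design
#'
#' Constructs the batch-by-type presence structure and compositions for the
#' named design families:
#' \describe{
#'   \item{complete}{every cell type is present in every batch.}
#'   \item{reference_panel}{one reference batch contains all K types; every
#'     other batch contains at least two.}
#'   \item{chain_type}{every two consecutive batches share at least two
#'     types and the union of all batches covers all K types.}
#'   \item{custom}{presence taken as given; only basic sanity (every type
#'     somewhere, every batch non-empty) is enforced. Use
#'     \code{\link{checkDesign}} to test identifiability.}
#' }
#' Compositions are drawn as a Dirichlet over the present types of each
#' batch (seeded) unless \code{pi} is supplied.
#'
#' @param kind design family.
#' @param B,K number of batches and cell types.
#' @param nPerBatch integer vector of per-batch cell counts.
#' @param presence optional B x K logical matrix; required for
#'   \code{custom}, validated against the family definition otherwise.
#' @param pi optional B x K composition matrix, or \code{"balanced"} for
#'   compositions that equalize the expected number of cells per type
#'   across the study (useful when rare edge types of a chain design would
#'   otherwise be starved of cells).
#' @param concentration Dirichlet concentration for drawn compositions.
#' @param reference index of the reference batch (reference_panel only).
#' @param seed seed for drawn presence/compositions.
#' @return A \linkS4class{BatchDesign}.
#' @examples
#' d <- buildDesign("chain_type", B = 4, K = 5, nPerBatch = c(30, 30, 20, 20))
#' checkDesign(d)
#' @export
buildDesign <- function(kind = c("complete", "reference_panel", "chain_type",
                                 "custom"),
                        B, K, nPerBatch, presence = NULL, pi = NULL,
                        concentration = 5, reference = 1L, seed = 1L) {
  kind <- match.arg(kind)
  B <- as.integer(B); K <- as.integer(K)
  nPerBatch <- as.integer(nPerBatch)
  if (length(nPerBatch) != B) stop("nPerBatch must have length B")

  if (is.null(presence)) {
    presence <- switch(kind,
      complete = matrix(TRUE, B, K),
      reference_panel = .withSeed(seed, {
        pr <- matrix(FALSE, B, K)
        pr[reference, ] <- TRUE
        for (b in seq_len(B)[-reference]) {
          sz <- sample(2:K, 1)
          pr[b, sample(K, sz)] <- TRUE
        }
        pr
      }),
      chain_type = .chainPresence(B, K),
      custom = .designViolation("custom designs require an explicit presence matrix"))
  } else {
    presence <- matrix(as.logical(presence), B, K)
  }
  .validatePresence(kind, presence, reference)

  if (is.null(pi)) {
    pi <- .withSeed(if (is.null(seed)) NULL else seed + 1L, {
      pp <- matrix(0, B, K)
      for (b in seq_len(B)) {
        idx <- which(presence[b, ])
        pp[b, idx] <- .rdirichlet1(rep(concentration, length(idx)))
      }
      pp
    })
  } else if (identical(pi, "balanced")) {
    # compositions that equalize the expected total cells per type across
    # the whole study (iterative proportional fitting over the presence
    # mask), so types present in few batches are not starved of cells
    pp <- presence * 1
    target <- sum(nPerBatch) / K
    for (it in 1:200) {
      colTot <- as.numeric(crossprod(pp, nPerBatch))
      pp <- sweep(pp, 2, ifelse(colTot > 0, target / colTot, 0), "*")
      pp <- pp / rowSums(pp)
    }
    # blend with the uniform-over-present composition so that no batch
    # degenerates to a single type (which would sever the realized
    # type-sharing between consecutive batches)
    unif <- presence / rowSums(presence)
    pi <- (pp + unif) / 2
  } else {
    pi <- matrix(as.numeric(pi), B, K)
  }
  new("BatchDesign", kind = kind, presence = presence, pi = pi,
      nPerBatch = nPerBatch)
}

# default chain-type presence: length-w windows spread across 1..K so that
# consecutive windows shift by at most w - 2 (hence share >= 2 types)
.chainPresence <- function(B, K) {
  if (B < 2) .designViolation("chain_type designs require B >= 2")
  if (K < 2) .designViolation("chain_type designs require K >= 2")
  pr <- matrix(FALSE, B, K)
  if (K == 2) {
    pr[] <- TRUE
    return(pr)
  }
  w <- max(3L, K - B + 2L)
  starts <- 1L + as.integer(round((seq_len(B) - 1L) * (K - w) / (B - 1L)))
  for (b in seq_len(B)) pr[b, starts[b]:(starts[b] + w - 1L)] <- TRUE
  pr
}

.validatePresence <- function(kind, presence, reference) {
  B <- nrow(presence); K <- ncol(presence)
  if (any(colSums(presence) == 0))
    .designViolation("every cell type must be present in at least one batch")
  if (any(rowSums(presence) == 0))
    .designViolation("every batch must contain at least one cell type")
  if (kind == "complete" && !all(presence))
    .designViolation("a complete design must have all types in all batches")
  if (kind == "reference_panel") {
    if (!all(presence[reference, ]))
      .designViolation("the reference batch must contain all cell types")
    other <- setdiff(seq_len(B), reference)
    if (length(other) && any(rowSums(presence[other, , drop = FALSE]) < 2))
      .designViolation("non-reference batches must contain at least two types")
  }
  if (kind == "chain_type") {
    if (B < 2) .designViolation("chain_type designs require B >= 2")
    for (b in 2:B) {
      sh <- sum(presence[b - 1, ] & presence[b, ])
      if (sh < 2)
        .designViolation("consecutive batches ", b - 1, " and ", b,
                         " share ", sh, " type(s); chain designs need >= 2")
    }
  }
  invisible(TRUE)
}

#' Batch graph and identifiability certificate of a design
#'
#' Builds the graph with one node per batch and an edge between two batches
#' exactly when they share at least two cell types. A connected graph (plus
#' the standing conditions: negative dropout slope, at least two DE genes
#' per type pair, distinct effect-difference vectors) certifies that the
#' model is identifiable up to label switching. Single-batch designs are
#' trivially connected.
#'
#' @param design a \linkS4class{BatchDesign}.
#' @return A \linkS4class{BatchGraph}.
#' @export
checkDesign <- function(design) {
  stopifnot(is(design, "BatchDesign"))
  pr <- design@presence
  B <- nrow(pr)
  pairs <- if (B >= 2) utils::combn(B, 2) else matrix(integer(0), 2, 0)
  shared <- integer(0)
  edges <- matrix(integer(0), ncol = 2)
  if (ncol(pairs)) {
    sh <- apply(pairs, 2, function(p) sum(pr[p[1], ] & pr[p[2], ]))
    keep <- sh >= 2
    edges <- t(pairs[, keep, drop = FALSE])
    shared <- as.integer(sh[keep])
  }
  connected <- if (B == 1) TRUE else {
    g <- igraph::make_empty_graph(n = B, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    igraph::is_connected(g)
  }
  new("BatchGraph", nBatches = B, edges = edges, shared = shared,
      connected = connected)
}

setMethod("show", "BatchGraph", function(object) {
  cat("BatchGraph:", object@nBatches, "batches,", nrow(object@edges),
      "edge(s);", if (object@connected) "connected (identifiable design)"
      else "NOT connected (design not certified identifiable)", "\n")
  if (nrow(object@edges))
    for (e in seq_len(nrow(object@edges)))
      cat(sprintf("  %d -- %d (%d shared types)\n", object@edges[e, 1],
                  object@edges[e, 2], object@shared[e]))
})

setMethod("show", "BatchDesign", function(object) {
  cat("BatchDesign (", object@kind, "): ", nrow(object@presence),
      " batches x ", ncol(object@presence), " types; n = (",
      paste(object@nPerBatch, collapse = ", "), ")\n", sep = "")
  for (b in seq_len(nrow(object@presence)))
    cat("  batch", b, ": types {",
        paste(which(object@presence[b, ]), collapse = ","), "}\n")
})
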