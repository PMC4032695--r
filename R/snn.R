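#' Synergetic neural network classifier
#'
#' Haken-style order-parameter pattern recognition. Training samples are
#' flattened, mean-centered, and l2-normalized; prototypes form the columns of
#' V; the adjoint V+ has rows biorthogonal to the prototypes (v_k+ v_j =
#' delta_kj), obtained by Moore-Penrose pseudoinversion or its penalized MPOD
#' (Most Probable Optimum Design) variant
#' v_p+ = E (V'V + P1*O + P2*I)^-1 V', with O the all-ones matrix, I the
#' identity, and E a block row-selector with one row of ones per class.
#' Classification projects a test sample onto the adjoint: the order
#' parameters eps_k = V+ q, and the largest order parameter wins (the fixed
#' point of the winner-take-all competition dynamics). "Melting" synthesizes
#' several samples of one class into a single regularized template.
#'
#' @name snn
NULL

#' Normalize a frame into a sample vector
#'
#' Flattens row-major, removes the mean, scales to unit l2 norm, so
#' sum(v) = 0 and sum(v^2) = 1.
#'
#' @param image numeric matrix (or already-flat numeric vector).
#' @return numeric sample vector.
#' @export
normalize_sample <- function(image) {
  v <- if (is.matrix(image)) as.vector(t(image)) else as.numeric(image)
  v <- v - mean(v)
  n2 <- sqrt(sum(v^2))
  if (n2 < 1e-12)
    stop("constant image: zero vector after centering", call. = FALSE)
  v / n2
}

#' Moore-Penrose adjoint of a prototype matrix
#'
#' Rows biorthogonal to V's columns: V_adj = (V'V)^-1 V', so V_adj V = I.
#'
#' @param V n x M numeric matrix of prototype columns, full column rank.
#' @return M x n adjoint matrix.
#' @export
moore_penrose_adjoint <- function(V) {
  stopifnot(is.matrix(V))
  M <- ncol(V)
  qrV <- qr(V)
  if (qrV$rank < M) {
    bad <- setdiff(seq_len(M), sort(qrV$pivot[seq_len(qrV$rank)]))
    stop("rank-deficient prototype matrix; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  solve(crossprod(V), t(V))
}

#' MPOD-penalized class adjoint
#'
#' v_p+ = E (V'V + P1*O + P2*I)^-1 V', with O the all-ones M x M matrix, I the
#' identity, and E the block row-selector built from `group_sizes` (one row of
#' ones over each class's columns). With P1 = P2 = 0 and singleton groups this
#' reduces to the Moore-Penrose adjoint.
#'
#' @param V n x M prototype matrix.
#' @param P1,P2 penalty coefficients (>= 0).
#' @param group_sizes integer vector of per-class column counts summing to M;
#'   default: one group per column.
#' @return length(group_sizes) x n adjoint matrix (one row per class).
#' @export
mpod_adjoint <- function(V, P1 = 0, P2 = 0, group_sizes = rep(1L, ncol(V))) {
  stopifnot(is.matrix(V), P1 >= 0, P2 >= 0)
  M <- ncol(V)
  if (sum(group_sizes) != M)
    stop("group_sizes must sum to ncol(V)", call. = FALSE)
  G <- crossprod(V) + P1 * matrix(1, M, M) + P2 * diag(M)
  adj <- tryCatch(solve(G, t(V)),
                  error = function(e) stop("regularized Gram matrix is ",
                                           "numerically singular", call. = FALSE))
  E <- matrix(0, length(group_sizes), M)
  off <- 0L
  for (g in seq_along(group_sizes)) {
    E[g, off + seq_len(group_sizes[g])] <- 1
    off <- off + group_sizes[g]
  }
  E %*% adj
}

#' Build a prototype bank
#'
#' @param V n x M matrix of normalized prototype columns.
#' @param labels class label per column (length M).
#' @param penalty NULL for the Moore-Penrose adjoint (rows = prototypes), or
#'   list(P1, P2) for the MPOD class adjoint (rows = classes, grouped by
#'   `labels` in order of first appearance).
#' @return a `prototype_bank`: V, V_adj, labels, row_labels, penalty.
#' @export
prototype_bank <- function(V, labels, penalty = NULL) {
  stopifnot(is.matrix(V), length(labels) == ncol(V))
  if (is.null(penalty)) {
    V_adj <- moore_penrose_adjoint(V)
    row_labels <- labels
  } else {
    classes <- unique(labels)
    ord <- order(match(labels, classes))
    V <- V[, ord, drop = FALSE]
    labels <- labels[ord]
    sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    V_adj <- mpod_adjoint(V, penalty$P1, penalty$P2, sizes)
    row_labels <- classes
  }
  structure(list(V = V, V_adj = V_adj, labels = labels,
                 row_labels = row_labels, penalty = penalty),
            class = "prototype_bank")
}

#' Order parameters and classification
#'
#' eps = V_adj q; the predicted label is the row label of the maximal order
#' parameter (ties: lowest row index).
#'
#' @param q sample vector (length n).
#' @param bank a `prototype_bank`.
#' @return list(eps = named numeric, label = predicted label).
#' @export
order_parameters <- function(q, bank) {
  stopifnot(inherits(bank, "prototype_bank"))
  if (length(q) != ncol(bank$V_adj))
    stop("sample length ", length(q), " does not match bank dimension ",
         ncol(bank$V_adj), call. = FALSE)
  eps <- drop(bank$V_adj %*% q)
  names(eps) <- bank$row_labels
  list(eps = eps, label = bank$row_labels[which.max(eps)])
}

#' Melt samples into one synthesized template
#'
#' Builds V from the samples as a single class, computes the MPOD class-row
#' adjoint, and renormalizes the resulting sample-space vector (centered, unit
#' norm). Melting one sample (or identical copies) returns that sample.
#'
#' @param samples list of equal-length normalized sample vectors (>= 1).
#' @param P1,P2 MPOD penalties used for the synthesis.
#' @return normalized sample vector.
#' @export
melt <- function(samples, P1 = 0.1, P2 = 0.1) {
  if (length(samples) == 0L) stop("no samples to melt", call. = FALSE)
  lens <- vapply(samples, length, integer(1))
  stopifnot(all(lens == lens[1]))
  if (length(samples) == 1L) return(samples[[1]])
  V <- do.call(cbind, samples)
  row <- drop(mpod_adjoint(V, P1, P2, group_sizes = ncol(V)))
  normalize_sample(row)
}

#' Build per-action prototype sets by two-stage melting
#'
#' Stage 1: for every snippet index, melt the normalized frames across
#' subjects into a snippet prototype P_s. Stage 2: melt the snippet
#' prototypes into one final prototype F per action. Both the snippet
#' prototypes and the final prototype are retained.
#'
#' @param training_map nested list: action -> snippet -> list of subject
#'   frames (matrices) or sample vectors.
#' @param P1,P2 MPOD penalties for both melting stages.
#' @return named list per action: list(P = list of snippet prototypes,
#'   F = final prototype).
#' @export
build_action_prototypes <- function(training_map, P1 = 0.1, P2 = 0.1) {
  stopifnot(is.list(training_map), length(training_map) > 0L)
  out <- list()
  for (action in names(training_map)) {
    snippets <- training_map[[action]]
    if (length(snippets) == 0L)
      stop("action '", action, "' has no snippets", call. = FALSE)
    P <- vector("list", length(snippets))
    for (s in seq_along(snippets)) {
      subj <- snippets[[s]]
      if (length(subj) == 0L)
        stop("action '", action, "', snippet ", s, ": no subject frames",
             call. = FALSE)
      vecs <- lapply(subj, function(x)
        if (is.matrix(x)) normalize_sample(x) else as.numeric(x))
      P[[s]] <- melt(vecs, P1, P2)
    }
    Fp <- melt(P, P1, P2)
    out[[action]] <- list(P = P, F = Fp)
  }
  out
}
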