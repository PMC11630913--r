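#' Construct a signed gene regulatory network
#'
#' A GRN is a signed directed graph: edges `(regulator, target, sign)` with
#' sign +1 (activation) or -1 (repression). Each gene's Boolean rule is
#' derived from its incoming edges with repressor-dominant semantics: the
#' target is ON iff (it has no activators OR at least one activator is ON)
#' AND every repressor is OFF.
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`
#'   (+1/-1). Exact duplicate edges are collapsed; duplicate
#'   (regulator, target) pairs with conflicting signs are an error.
#' @param genes optional gene universe (ordered, unique); defaults to the
#'   order of first appearance in the edge list (regulator before target).
#' @return an object of class `grn` with fields `genes` and `edges`.
#' @export
#' @examples
#' g <- grn(data.frame(regulator = c("A", "B"), target = c("B", "A"),
#'                     sign = c(-1, -1)))   # toggle switch
#' g
grn <- function(edges, genes = NULL) {
  if (!is.data.frame(edges)) stopf("edges must be a data.frame")
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(edges))) {
    stopf("edge table must have columns %s", paste(need, collapse = ", "))
  }
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      sign = as.integer(edges$sign),
                      stringsAsFactors = FALSE)
  if (any(!edges$sign %in% c(-1L, 1L))) stopf("edge signs must be +1 or -1")
  edges <- unique(edges)
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- unique(key[duplicated(key)])
    stopf("conflicting signs for duplicated edge(s): %s",
          paste(gsub("\r", " -> ", bad), collapse = ", "))
  }
  appear <- unique(as.vector(t(as.matrix(edges[, c("regulator", "target")]))))
  if (is.null(genes)) {
    genes <- appear
  } else {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) stopf("duplicate gene ids")
    if (!all(appear %in% genes)) {
      stopf("edge genes outside gene universe: %s",
            paste(setdiff(appear, genes), collapse = ", "))
    }
  }
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d genes, %d edges (%d activating, %d repressing)\n",
              length(x$genes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

# per-gene regulator index lists under the gene ordering of the grn
rule_table <- function(g) {
  stopifnot(inherits(g, "grn"))
  idx <- stats::setNames(seq_along(g$genes), g$genes)
  act <- rep(list(integer(0)), length(g$genes))
  rep_ <- rep(list(integer(0)), length(g$genes))
  for (i in seq_len(nrow(g$edges))) {
    t <- idx[[g$edges$target[i]]]
    r <- idx[[g$edges$regulator[i]]]
    if (g$edges$sign[i] == 1L) act[[t]] <- c(act[[t]], r) else rep_[[t]] <- c(rep_[[t]], r)
  }
  list(act = act, rep = rep_, genes = g$genes)
}

# every gene must have >= 1 regulator (self-edges count) for simulation
check_simulable <- function(g) {
  regulated <- unique(g$edges$target)
  orphan <- setdiff(g$genes, regulated)
  if (length(orphan)) {
    stopf(paste0("gene(s) without any regulator: %s. Every gene in a ",
                 "simulated network must have at least one regulator ",
                 "(a self-activator counts)."),
          paste(orphan, collapse = ", "))
  }
  invisible(TRUE)
}

# synchronous application of every gene's rule to a 0/1 state vector
boolean_update <- function(rt, state) {
  n <- length(rt$genes)
  out <- integer(n)
  for (gi in seq_len(n)) {
    a <- rt$act[[gi]]
    r <- rt$rep[[gi]]
    on <- (length(a) == 0L || any(state[a] == 1L)) && all(state[r] == 0L)
    out[gi] <- as.integer(on)
  }
  out
}

#' Read a signed GRN from a CSV edge list
#'
#' Expects columns `regulator`, `target`, `sign` with sign given as
#' `+1`/`1`/`-1` or the tokens `activation`/`repression`.
#'
#' @param path CSV path.
#' @return a [grn()].
#' @export
read_grn <- function(path) {
  if (!file.exists(path)) stopf("GRN file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(df))) {
    stopf("GRN edge list must have columns %s", paste(need, collapse = ", "))
  }
  tok <- trimws(as.character(df$sign))
  sign <- ifelse(tok %in% c("1", "+1", "activation"), 1L,
                 ifelse(tok %in% c("-1", "repression"), -1L, NA_integer_))
  if (any(is.na(sign))) {
    stopf("unknown sign token(s): %s (accepted: +1, 1, -1, activation, repression)",
          paste(unique(tok[is.na(sign)]), collapse = ", "))
  }
  grn(data.frame(regulator = df$regulator, target = df$target, sign = sign))
}

#' Write a signed GRN to a CSV edge list
#'
#' @param g a [grn()].
#' @param path output CSV path.
#' @return invisibly, `path`. `read_grn(write_grn(g, path))` reproduces the
#'   edge set and gene order of `g` (for networks whose genes all appear in
#'   an edge).
#' @export
write_grn <- function(g, path) {
  stopifnot(inherits(g, "grn"))
  write.csv(g$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
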