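#' @title Ontology DAG construction and pruning
#' @name ontology
#' @description Parse an OBO ontology into a rooted DAG, attach gene
#'   annotations, and prune terms whose descendant closure contains no
#'   annotated gene. The pruned DAG is the wiring diagram from which the
#'   expression encoder is compiled.
NULL

new_ontology_dag <- function(terms, root, child_edges, gene_annotations,
                             depth, topo_order, genes = character(0)) {
  structure(
    list(
      terms = terms,
      root = root,
      child_edges = child_edges,
      gene_annotations = gene_annotations,
      depth = depth,
      topo_order = topo_order,
      genes = genes
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms, root", x$root,
      "| max depth", if (length(x$depth)) max(unlist(x$depth)) else 0,
      "|", length(x$genes), "annotated genes\n")
  invisible(x)
}

# Kahn topological sort, children before parents, lexicographic tie-break.
# parent_edges: named list term -> character vector of parents.
.topo_sort <- function(terms, parent_edges) {
  # out-degree in the child->parent orientation = number of parents
  child_of <- stats::setNames(vector("list", length(terms)), terms)
  n_children <- stats::setNames(integer(length(terms)), terms)
  for (t in terms) {
    for (p in parent_edges[[t]]) {
      child_of[[p]] <- c(child_of[[p]], t)
      n_children[[t]] <- n_children[[t]] # no-op, children counted below
    }
  }
  pending <- stats::setNames(integer(length(terms)), terms)
  for (t in terms) pending[[t]] <- length(child_of[[t]])
  queue <- sort(terms[pending[terms] == 0L])
  order <- character(0)
  while (length(queue)) {
    t <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, t)
    for (p in parent_edges[[t]]) {
      pending[[p]] <- pending[[p]] - 1L
      if (pending[[p]] == 0L) queue <- sort(c(queue, p))
    }
  }
  if (length(order) != length(terms)) {
    cyclic <- setdiff(terms, order)
    stop("cycle detected in ontology involving term ", cyclic[1L])
  }
  order
}

.compute_depth <- function(terms, child_edges, root) {
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  depth[[root]] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character(0)
    for (t in frontier) {
      for (ch in child_edges[[t]]) {
        if (is.na(depth[[ch]])) {
          depth[[ch]] <- d # BFS => shortest path for multi-parent terms
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  depth
}

#' Parse an OBO file into an ontology DAG
#'
#' Reads \code{[Term]} stanzas, using only \code{is_a} relationships as
#' edges (obsolete terms are skipped). Edges are reversed into per-term
#' child lists with deterministic lexicographic ordering, so downstream
#' weight layouts are reproducible.
#'
#' @param path Path to an OBO 1.2/1.4 file.
#' @return An \code{ontology_dag} with empty gene annotations.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0)
  parent_edges <- list()
  for (i in seq_along(stanza_starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    # stanzas end at the next header
    next_hdr <- grep("^\\[", block[-1L])
    if (length(next_hdr)) block <- block[seq_len(next_hdr[1L])]
    get_vals <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*(!.*)?$", "", v) # strip trailing comments
    }
    id <- get_vals("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    isa <- vapply(get_vals("is_a"), function(x) strsplit(x, "\\s+")[[1L]][1L],
                  character(1), USE.NAMES = FALSE)
    ids <- c(ids, id)
    parent_edges[[id]] <- unique(isa)
  }
  terms <- sort(unique(ids))
  # drop dangling parents (e.g. obsolete or other-namespace targets)
  parent_edges <- lapply(parent_edges[terms],
                         function(p) intersect(p, terms))
  roots <- terms[vapply(parent_edges, length, 1L) == 0L]
  if (length(roots) == 0L) {
    # every term has a parent => there must be a cycle; report via topo sort
    .topo_sort(terms, parent_edges)
    stop("ontology has no root term")
  }
  if (length(roots) > 1L) {
    stop("ontology has multiple root candidates: ",
         paste(roots, collapse = ", "))
  }
  topo <- .topo_sort(terms, parent_edges)
  child_edges <- stats::setNames(
    lapply(terms, function(t) character(0)), terms)
  for (t in terms) {
    for (p in parent_edges[[t]]) child_edges[[p]] <- c(child_edges[[p]], t)
  }
  child_edges <- lapply(child_edges, sort)
  depth <- .compute_depth(terms, child_edges, roots)
  new_ontology_dag(
    terms = terms, root = roots, child_edges = child_edges,
    gene_annotations = stats::setNames(
      lapply(terms, function(t) character(0)), terms),
    depth = depth, topo_order = topo
  )
}

#' Attach gene annotations and prune unsupported terms
#'
#' Keeps only genes present in \code{gene_list}, attaches each to the terms
#' it is directly annotated to, and removes every term whose descendant
#' closure contains no annotated gene. Root, depths, and topological order
#' are recomputed on the pruned graph. The operation is idempotent.
#'
#' @param dag An \code{ontology_dag} from [parse_obo()].
#' @param annotations Data frame with columns \code{gene_id},
#'   \code{term_id} (direct annotations).
#' @param gene_list Character vector of genes the expression matrix provides.
#' @return A pruned \code{ontology_dag}; genes lacking annotation are
#'   reported via a message and recorded in \code{attr(,"dropped_genes")}.
#' @export
annotate_and_prune <- function(dag, annotations, gene_list) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!nrow(annotations)) stop("annotation table is empty")
  if (!length(gene_list)) stop("gene_list is empty")
  ann <- annotations[annotations$gene_id %in% gene_list &
                       annotations$term_id %in% dag$terms, , drop = FALSE]
  kept_genes <- sort(unique(ann$gene_id))
  dropped <- sort(setdiff(gene_list, kept_genes))
  if (length(dropped)) {
    message(length(dropped), " gene(s) in gene_list lack any annotation: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  if (!length(kept_genes)) stop("empty annotated ontology")
  direct <- stats::setNames(
    lapply(dag$terms, function(t) character(0)), dag$terms)
  for (t in unique(ann$term_id)) {
    direct[[t]] <- sort(unique(ann$gene_id[ann$term_id == t]))
  }
  # genes in descendant closure, accumulated children-first
  closure_n <- stats::setNames(integer(length(dag$terms)), dag$terms)
  closure <- stats::setNames(
    lapply(dag$terms, function(t) character(0)), dag$terms)
  for (t in dag$topo_order) {
    g <- direct[[t]]
    for (ch in dag$child_edges[[t]]) g <- c(g, closure[[ch]])
    closure[[t]] <- unique(g)
    closure_n[[t]] <- length(closure[[t]])
  }
  keep <- dag$terms[closure_n[dag$terms] > 0L]
  if (!length(keep)) stop("empty annotated ontology")
  child_edges <- lapply(dag$child_edges[keep],
                        function(ch) sort(intersect(ch, keep)))
  # terms kept form an ancestor-closed set, so the old root survives
  parent_edges <- stats::setNames(lapply(keep, function(t) character(0)), keep)
  for (t in keep) {
    for (ch in child_edges[[t]]) {
      parent_edges[[ch]] <- c(parent_edges[[ch]], t)
    }
  }
  roots <- keep[vapply(parent_edges[keep], length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop("pruned ontology does not have a unique root: ",
         paste(roots, collapse = ", "))
  }
  topo <- .topo_sort(keep, parent_edges)
  depth <- .compute_depth(keep, child_edges, roots)
  out <- new_ontology_dag(
    terms = keep, root = roots, child_edges = child_edges,
    gene_annotations = direct[keep],
    depth = depth, topo_order = topo, genes = kept_genes
  )
  attr(out, "dropped_genes") <- dropped
  out
}

#' Genes in the descendant closure of a term
#' @param dag An annotated \code{ontology_dag}.
#' @param term Term id.
#' @return Character vector of gene ids.
#' @export
term_gene_closure <- function(dag, term) {
  stopifnot(term %in% dag$terms)
  seen <- character(0)
  frontier <- term
  genes <- character(0)
  while (length(frontier)) {
    t <- frontier[1L]
    frontier <- frontier[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    genes <- c(genes, dag$gene_annotations[[t]])
    frontier <- c(frontier, dag$child_edges[[t]])
  }
  sort(unique(genes))
}

#' Validate ontology DAG invariants
#'
#' Checks acyclicity (via the stored topological order), unique root,
#' children-before-parents ordering, the shortest-path depth recursion, and
#' (when annotated) non-empty gene closures for every term.
#'
#' @param dag An \code{ontology_dag}.
#' @return \code{TRUE} invisibly; stops on violation.
#' @export
validate_ontology <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!setequal(dag$topo_order, dag$terms) ||
      length(dag$topo_order) != length(dag$terms)) {
    stop("topo_order does not enumerate terms exactly once")
  }
  pos <- stats::setNames(seq_along(dag$topo_order), dag$topo_order)
  for (t in dag$terms) {
    for (ch in dag$child_edges[[t]]) {
      if (pos[[ch]] >= pos[[t]]) stop("child ", ch, " not before parent ", t)
    }
  }
  if (dag$depth[[dag$root]] != 0L) stop("root depth must be 0")
  parent_of <- stats::setNames(
    lapply(dag$terms, function(t) character(0)), dag$terms)
  for (t in dag$terms) {
    for (ch in dag$child_edges[[t]]) {
      parent_of[[ch]] <- c(parent_of[[ch]], t)
    }
  }
  for (t in dag$terms) {
    if (t == dag$root) next
    ps <- parent_of[[t]]
    if (!length(ps)) stop("non-root term ", t, " has no parent")
    want <- 1L + min(vapply(ps, function(p) dag$depth[[p]], 1L))
    if (dag$depth[[t]] != want) stop("depth invariant violated at ", t)
  }
  if (length(dag$genes)) {
    for (t in dag$terms) {
      if (!length(term_gene_closure(dag, t))) {
        stop("term ", t, " has no annotated gene in its closure")
      }
    }
  }
  invisible(TRUE)
}

#' Export a pruned DAG as JSON for provenance
#' @param dag An \code{ontology_dag}.
#' @param path Output file path.
#' @export
dag_to_json <- function(dag, path) {
  jsonlite::write_json(
    list(
      root = dag$root,
      terms = dag$terms,
      child_edges = dag$child_edges,
      gene_annotations = dag$gene_annotations,
      depth = as.list(dag$depth),
      topo_order = dag$topo_order,
      genes = dag$genes
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

# Stable content hash of the DAG structure; used to guard stage transfer.
dag_hash <- function(dag) {
  desc <- paste(
    dag$root,
    paste(vapply(dag$terms, function(t) {
      paste0(t, ">", paste(dag$child_edges[[t]], collapse = ","),
             "|", paste(dag$gene_annotations[[t]], collapse = ","))
    }, character(1)), collapse = ";"),
    sep = "#")
  ints <- utf8ToInt(desc)
  h <- 17
  for (x in ints) h <- (h * 1000003 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Read a two-column gene annotation TSV
#' @param path TSV with columns \code{gene_id}, \code{term_id}.
#' @return Data frame with those columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    stop("annotation table must have columns gene_id, term_id")
  }
  df[, c("gene_id", "term_id")]
}
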