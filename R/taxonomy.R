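#' Validate a taxonomy table
#'
#' A taxonomy is a rooted tree stored as a four-column data frame:
#' `node_id`, `parent_id`, `rank`, `name`. The root is the single node whose
#' parent is itself. Used for copy-number propagation/imputation and for the
#' rank aggregation that produces class-level tables with "Nc." and "U."
#' pseudo-taxa.
#'
#' @param tax data frame with columns `node_id`, `parent_id`, `rank`, `name`.
#' @return `tax` with character ids, invisibly checked for: exactly one root,
#'   every non-root parent present, and no cycles.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("node_id", "parent_id", "rank", "name")
  if (!is.data.frame(tax) || !all(need %in% names(tax))) {
    stop("taxonomy must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  tax$node_id <- as.character(tax$node_id)
  tax$parent_id <- as.character(tax$parent_id)
  if (anyDuplicated(tax$node_id)) stop("duplicate taxonomy node ids")
  root <- tax$node_id[tax$node_id == tax$parent_id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (parent_id == node_id), found ",
         length(root))
  }
  missing_parent <- setdiff(tax$parent_id, tax$node_id)
  if (length(missing_parent) > 0) {
    stop("parent ids not present as nodes: ",
         paste(missing_parent, collapse = ", "))
  }
  # walk every node to the root; revisiting a node means a cycle
  parent_of <- stats::setNames(tax$parent_id, tax$node_id)
  for (id in tax$node_id) {
    seen <- character()
    cur <- id
    while (cur != parent_of[[cur]]) {
      if (cur %in% seen) stop("cycle in taxonomy involving node ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(tax)
}

taxonomy_root <- function(tax) tax$node_id[tax$node_id == tax$parent_id]

#' Lineage of a node, from itself up to the root
#' @param tax validated taxonomy table.
#' @param node_id node to trace.
#' @return character vector of node ids, `node_id` first, root last.
#' @export
taxonomy_lineage <- function(tax, node_id) {
  parent_of <- stats::setNames(tax$parent_id, tax$node_id)
  if (!node_id %in% tax$node_id) stop("unknown taxonomy node: ", node_id)
  path <- node_id
  cur <- node_id
  while (cur != parent_of[[cur]]) {
    cur <- parent_of[[cur]]
    path <- c(path, cur)
  }
  path
}

#' Propagate a leaf attribute up a taxonomy by averaging children
#'
#' Computes, bottom-up, each internal node's attribute as the arithmetic mean
#' of its children's (already propagated) values — the scheme used to assign
#' average rRNA copy numbers to higher taxonomic levels from species-level
#' measurements. Children with no value anywhere below them are ignored;
#' a node with no valued descendants and no own value stays missing.
#'
#' @param tax validated taxonomy table.
#' @param values named numeric vector of known attribute values, names are
#'   node ids (typically species). A node's own supplied value takes
#'   precedence over the average of its children.
#' @return named numeric vector over all nodes that could be valued.
#' @export
propagate_attribute_up <- function(tax, values) {
  tax <- validate_taxonomy(tax)
  if (length(values) == 0 || is.null(names(values))) {
    stop("'values' must be a named numeric vector of node attributes")
  }
  unknown <- setdiff(names(values), tax$node_id)
  if (length(unknown) > 0) {
    stop("valued nodes absent from taxonomy: ", paste(unknown, collapse = ", "))
  }
  children <- split(tax$node_id, tax$parent_id)
  root <- taxonomy_root(tax)
  children[[root]] <- setdiff(children[[root]], root)
  out <- new.env(parent = emptyenv())
  resolve <- function(id) {
    if (!is.null(out[[id]])) return(out[[id]])
    if (id %in% names(values)) {
      out[[id]] <- unname(values[[id]])
      return(out[[id]])
    }
    kids <- children[[id]]
    if (is.null(kids) || length(kids) == 0) {
      out[[id]] <- NA_real_
      return(NA_real_)
    }
    kv <- vapply(kids, resolve, numeric(1))
    kv <- kv[!is.na(kv)]
    out[[id]] <- if (length(kv) > 0) mean(kv) else NA_real_
    out[[id]]
  }
  res <- vapply(tax$node_id, resolve, numeric(1))
  res[!is.na(res)]
}

#' Fill missing node attributes from the nearest valued ancestor
#'
#' After [propagate_attribute_up()], every target node lacking a value
#' receives the propagated value of its nearest ancestor that has one — the
#' "average of closely related species from the above taxonomic level" rule
#' used for missing genome sizes and 16S copy numbers.
#'
#' @param tax validated taxonomy table.
#' @param values named numeric vector of known values (any nodes).
#' @param target_nodes node ids that must end up valued (default: all nodes
#'   named in `values` plus all leaves).
#' @return named numeric vector covering every target node.
#' @export
impute_missing_attribute <- function(tax, values, target_nodes = NULL) {
  tax <- validate_taxonomy(tax)
  prop <- propagate_attribute_up(tax, values)
  if (is.null(target_nodes)) {
    target_nodes <- setdiff(tax$node_id, tax$parent_id) # leaves
    target_nodes <- union(target_nodes, names(values))
  }
  unknown <- setdiff(target_nodes, tax$node_id)
  if (length(unknown) > 0) {
    stop("target nodes absent from taxonomy: ", paste(unknown, collapse = ", "))
  }
  out <- numeric(length(target_nodes))
  names(out) <- target_nodes
  for (id in target_nodes) {
    if (id %in% names(prop)) {
      out[[id]] <- prop[[id]]
      next
    }
    lineage <- taxonomy_lineage(tax, id)[-1]
    hit <- lineage[lineage %in% names(prop)]
    if (length(hit) == 0) {
      stop("no valued ancestor for node ", id, "; cannot impute")
    }
    out[[id]] <- prop[[hit[1]]]
  }
  out
}

#' Aggregate a feature table to a taxonomic rank with Nc./U. handling
#'
#' Rolls feature abundances up to a target rank (typically class). Features
#' whose lineage contains a node of the target rank are summed into that
#' node's name. Leaf-side features whose lineage skips the target rank are
#' summed under `"Nc. <ancestor>"` (No class), named after the nearest
#' ancestor ranked above the target; abundance assigned directly to that
#' ancestor is not included. Features sitting on internal nodes ranked
#' strictly between the target rank and the root keep their own name with a
#' `"U. "` (Unknown) prefix. Abundance assigned to the root itself is dropped
#' and the dropped fraction is reported as an attribute.
#'
#' @param table stations x features matrix; column names must be taxonomy
#'   node ids.
#' @param tax validated taxonomy table.
#' @param rank target rank label, e.g. `"class"`.
#' @param rank_order character vector of rank labels ordered leaf to root;
#'   ranks not listed are treated as leaf-side.
#' @return aggregated stations x groups matrix with attribute
#'   `dropped_fraction` (share of total abundance assigned to the root).
#' @export
aggregate_to_rank <- function(table, tax, rank,
                              rank_order = c("species", "genus", "class",
                                             "phylum", "domain")) {
  validate_feature_table(table)
  tax <- validate_taxonomy(tax)
  if (!rank %in% rank_order) stop("target rank must appear in rank_order")
  unmapped <- setdiff(colnames(table), tax$node_id)
  if (length(unmapped) > 0) {
    stop("features absent from taxonomy: ", paste(unmapped, collapse = ", "))
  }
  rank_of <- stats::setNames(tax$rank, tax$node_id)
  name_of <- stats::setNames(tax$name, tax$node_id)
  root <- taxonomy_root(tax)
  target_pos <- match(rank, rank_order)
  pos <- function(id) match(rank_of[[id]], rank_order) # NA for unlisted ranks

  group_of <- character(ncol(table))
  for (j in seq_len(ncol(table))) {
    id <- colnames(table)[j]
    if (id == root) {
      group_of[j] <- NA_character_ # dropped
      next
    }
    lineage <- taxonomy_lineage(tax, id)
    at_rank <- lineage[!is.na(vapply(lineage, pos, numeric(1))) &
                         vapply(lineage, pos, numeric(1)) == target_pos]
    if (length(at_rank) > 0) {
      group_of[j] <- name_of[[at_rank[1]]]
      next
    }
    own <- pos(id)
    if (!is.na(own) && own > target_pos) {
      # internal node strictly between the target rank and the root
      group_of[j] <- paste0("U. ", name_of[[id]])
      next
    }
    # leaf-side with no target-rank ancestor: nearest ancestor ranked above
    anc <- lineage[-1]
    anc <- anc[anc != root]
    anc_pos <- vapply(anc, pos, numeric(1))
    above <- anc[!is.na(anc_pos) & anc_pos > target_pos]
    if (length(above) == 0) {
      stop("feature ", id, " has no ancestor ranked above '", rank, "'")
    }
    group_of[j] <- paste0("Nc. ", name_of[[above[1]]])
  }

  total <- sum(table)
  dropped <- sum(table[, is.na(group_of), drop = FALSE])
  keep <- !is.na(group_of)
  groups <- unique(group_of[keep])
  out <- matrix(0, nrow(table), length(groups),
                dimnames = list(rownames(table), groups))
  for (g in groups) {
    out[, g] <- rowSums(table[, keep & group_of == g, drop = FALSE])
  }
  attr(out, "dropped_fraction") <- if (total > 0) dropped / total else 0
  out
}
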