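# Network I/O: extended Newick (eNewick, '#H' hybrid tags) and a lossless
# plain edge-list dialect. eNewick is the interchange standard; edge lists are
# the auditable fixture format (multi-parent topologies transcribe safely).

#' Parse an extended-Newick (eNewick) string
#'
#' Reticulate nodes are written in eNewick by tagging every occurrence with
#' the same `#H<id>` suffix; all occurrences are unified into a single node
#' whose children are collected across occurrences and whose parents are the
#' parents of the occurrences. Leaf names are taxon labels. Internal node
#' names, when present, become node ids; unnamed internal nodes receive
#' generated ids.
#'
#' @param text a single eNewick statement terminated by `;`.
#' @param name optional network name.
#' @return a validated [phylo_network].
#' @examples
#' parse_enewick("((1,(2)#H1)x,(#H1,3)y)r;")
#' @export
parse_enewick <- function(text, name = NULL) {
  s <- trimws(text)
  if (!nzchar(s)) stop_parse("empty eNewick string")
  if (substr(s, nchar(s), nchar(s)) != ";")
    stop_parse("eNewick statement must end with ';'", nchar(s))
  s <- substr(s, 1, nchar(s) - 1)

  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L

  # occurrence records
  occ <- list() # each: list(label, hyb, children = integer indices into occ)

  read_name <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c("(", ")", ",", ";")))
      advance()
    raw <- trimws(substr(s, start, pos - 1L))
    if (grepl("#", raw, fixed = TRUE)) {
      parts <- strsplit(raw, "#", fixed = TRUE)[[1]]
      label <- parts[1]
      tag <- paste(parts[-1], collapse = "#")
      if (!grepl("^H", tag)) stop_parse(sprintf("malformed hybrid tag '#%s'", tag), start)
      list(label = label, hyb = tag)
    } else {
      list(label = raw, hyb = NA_character_)
    }
  }

  parse_subtree <- function() {
    if (peek() == "(") {
      advance()
      kids <- integer(0)
      repeat {
        kids <- c(kids, parse_subtree())
        if (peek() == ",") { advance(); next }
        break
      }
      if (peek() != ")") stop_parse("expected ')' or ','", pos)
      advance()
      nm <- read_name()
      occ[[length(occ) + 1L]] <<- list(label = nm$label, hyb = nm$hyb,
                                       children = kids)
    } else {
      nm <- read_name()
      if (!nzchar(nm$label) && is.na(nm$hyb))
        stop_parse("expected a node", pos)
      occ[[length(occ) + 1L]] <<- list(label = nm$label, hyb = nm$hyb,
                                       children = integer(0))
    }
    length(occ)
  }

  root_i <- parse_subtree()
  if (pos <= n) stop_parse("trailing characters after statement", pos)

  # unify hybrid occurrences: group index -> final node
  hybs <- vapply(occ, function(o) o$hyb, character(1))
  group <- seq_along(occ)
  for (tag in unique(hybs[!is.na(hybs)])) {
    members <- which(hybs == tag)
    group[members] <- members[1]
  }

  auto <- 0L
  final_id <- character(length(occ))
  for (g in unique(group)) {
    members <- which(group == g)
    labels <- unique(Filter(nzchar, vapply(occ[members], `[[`, "", "label")))
    if (length(labels) > 1)
      stop_parse(sprintf("conflicting labels for hybrid '#%s': %s",
                         hybs[g], paste(labels, collapse = ", ")))
    kids <- unlist(lapply(occ[members], `[[`, "children"))
    is_leaf <- length(kids) == 0
    id <- if (length(labels) == 1 && is_leaf) {
      labels
    } else if (length(labels) == 1) {
      labels
    } else if (!is.na(hybs[g])) {
      hybs[g]
    } else {
      auto <- auto + 1L
      paste0("_", auto)
    }
    final_id[members] <- id
  }
  if (anyDuplicated(final_id[match(unique(group), group)]))
    stop_parse("duplicate node names in eNewick string")

  edges <- matrix(character(0), ncol = 2)
  labels <- character(0)
  for (g in unique(group)) {
    members <- which(group == g)
    kids <- unlist(lapply(occ[members], `[[`, "children"))
    for (ki in kids) edges <- rbind(edges, c(final_id[g], final_id[ki]))
    if (length(kids) == 0) {
      lab <- unique(Filter(nzchar, vapply(occ[members], `[[`, "", "label")))
      if (length(lab) == 0)
        stop_parse("leaf without a taxon label in eNewick string")
      labels[final_id[g]] <- lab
    }
  }
  phylo_network(edges, labels, nodes = unique(final_id), name = name)
}

#' Serialize a network to canonical eNewick
#'
#' Output is deterministic: children are emitted in a canonical order (by the
#' sorted set of taxon labels reachable below the child, ties broken by node
#' id), and each reticulate node is written in full at its first canonical
#' occurrence and as a bare `#H<i>` reference afterwards. Internal node ids
#' are not emitted, so a parse/serialize round trip preserves the network up
#' to isomorphism, not node naming.
#'
#' @param net a validated [phylo_network].
#' @return a single eNewick string terminated by `;`.
#' @export
write_enewick <- function(net) {
  idx <- network_index(net)
  nodes <- net$nodes
  # sorted label set below each node, as a key string
  below <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in rev(idx$topo)) {
    if (idx$outdeg[[v]] == 0) {
      below[[v]] <- unname(net$labels[[v]])
    } else {
      below[[v]] <- sort(unique(unlist(below[idx$children[[v]]])), method = "radix")
    }
  }
  key <- vapply(below, paste, "", collapse = "\x1f")

  tag_of <- new.env(parent = emptyenv())
  next_tag <- 0L

  emit <- function(v) {
    hyb <- idx$indeg[[v]] >= 2
    if (hyb && !is.null(tag_of[[v]])) return(paste0("#H", tag_of[[v]]))
    suffix <- ""
    if (hyb) {
      next_tag <<- next_tag + 1L
      tag_of[[v]] <- next_tag
      suffix <- paste0("#H", next_tag)
    }
    if (idx$outdeg[[v]] == 0) {
      paste0(net$labels[[v]], suffix)
    } else {
      ch <- idx$children[[v]]
      ch <- ch[order(key[ch], ch, method = "radix")]
      paste0("(", paste(vapply(ch, emit, ""), collapse = ","), ")", suffix)
    }
  }
  paste0(emit(idx$root), ";")
}

#' Parse the plain edge-list network format
#'
#' Line format: `edge <parent> <child>` declares a directed edge and
#' `leaf <node> <label>` a taxon label; `#` starts a comment; blank lines are
#' ignored. Node ids are preserved verbatim, which makes the format lossless.
#'
#' @param text edge-list text (single string, possibly multi-line).
#' @param name optional network name.
#' @return a validated [phylo_network].
#' @examples
#' parse_edgelist("edge r a\nedge r b\nleaf a 1\nleaf b 2")
#' @export
parse_edgelist <- function(text, name = NULL) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  edges <- matrix(character(0), ncol = 2)
  labels <- character(0)
  nodes <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (fields[1] == "edge") {
      if (length(fields) != 3)
        stop_parse(sprintf("line %d: 'edge' needs parent and child", i), i)
      edges <- rbind(edges, fields[2:3])
      nodes <- c(nodes, fields[2:3])
    } else if (fields[1] == "leaf") {
      if (length(fields) != 3)
        stop_parse(sprintf("line %d: 'leaf' needs node and label", i), i)
      labels[fields[2]] <- fields[3]
      nodes <- c(nodes, fields[2])
    } else if (fields[1] == "node") {
      if (length(fields) != 2)
        stop_parse(sprintf("line %d: 'node' needs an id", i), i)
      nodes <- c(nodes, fields[2])
    } else {
      stop_parse(sprintf("line %d: unknown directive '%s'", i, fields[1]), i)
    }
  }
  if (length(nodes) == 0) stop_parse("no network content found")
  phylo_network(edges, labels, nodes = unique(nodes), name = name)
}

#' Serialize a network to the edge-list format
#' @param net a validated [phylo_network].
#' @return a single string (lines separated by `\n`, trailing newline).
#' @export
write_edgelist <- function(net) {
  idx <- network_index(net)
  e <- net$edges
  lines <- character(0)
  if (nrow(e) > 0) {
    ord <- order(e[, 1], e[, 2], method = "radix")
    lines <- c(lines, sprintf("edge %s %s", e[ord, 1], e[ord, 2]))
  }
  leaves <- sort(idx$leaves, method = "radix")
  lines <- c(lines, sprintf("leaf %s %s", leaves, net$labels[leaves]))
  if (length(net$nodes) == 1 && nrow(e) == 0) {
    lines <- c(sprintf("node %s", net$nodes), lines)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

enewick_extensions <- c("nwk", "newick", "enwk", "enewick", "tre", "tree")

#' Read a network from a file
#'
#' The format is chosen by extension: `.nwk`, `.newick`, `.enwk`, `.enewick`,
#' `.tre` and `.tree` files are parsed as eNewick, anything else as the
#' edge-list format.
#'
#' @param path file path.
#' @param name optional network name; defaults to the file base name.
#' @return a validated [phylo_network].
#' @export
read_network <- function(path, name = NULL) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ext <- tolower(sub("^.*\\.", "", basename(path)))
  if (ext %in% enewick_extensions) parse_enewick(text, name = name)
  else parse_edgelist(text, name = name)
}

#' Write a network to a file
#'
#' Chooses eNewick or edge-list by the file extension, mirroring
#' [read_network()].
#'
#' @param net a validated [phylo_network].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  ext <- tolower(sub("^.*\\.", "", basename(path)))
  text <- if (ext %in% enewick_extensions) paste0(write_enewick(net), "\n")
          else write_edgelist(net)
  writeLines(sub("\n$", "", text), path)
  invisible(path)
}
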