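#' @useDynLib golgisim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif quantile sd wilcox.test setNames density
#' @importFrom utils read.delim write.table head modifyList
NULL

# Sugar identities.  "Sia" is accepted on input as a synonym for NeuAc and is
# the token emitted on output, matching the pathway notation strings.
.SUGARS <- c("GlcNAc", "NeuAc", "Man", "Gal", "Glc", "Fuc")
.SUGAR_TOKENS <- c(GlcNAc = "GlcNAc", NeuAc = "Sia", Man = "Man",
                   Gal = "Gal", Glc = "Glc", Fuc = "Fuc")

glycan_node <- function(sugar, linkage = "", children = list()) {
  list(sugar = sugar, linkage = linkage, children = children)
}

#' Construct a glycan structure object
#'
#' A glycan is a rooted, ordered tree of monosaccharide residues.  Each
#' residue carries a sugar identity (GlcNAc, Man, Gal, Fuc, NeuAc or Glc) and
#' the linkage code joining it to its parent (e.g. "4.1"; empty for the
#' root).  The reducing-end root of every pathway glycan is a GlcNAc.  The
#' `quenched` flag marks a glycan that has been withdrawn from processing
#' (oligomannose quench); a quenched glycan matches no enzyme rule.
#'
#' @param node nested list with fields `sugar`, `linkage`, `children`.
#' @param quenched logical flag.
#' @return An object of class `"glycan"`.
#' @export
glycan <- function(node, quenched = FALSE) {
  structure(node, quenched = isTRUE(quenched), class = "glycan")
}

is_quenched <- function(g) isTRUE(attr(g, "quenched"))

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", glycan_serialize(x),
      if (is_quenched(x)) "  [quenched]", "\n", sep = "")
  comp <- glycan_composition(x)
  cat("  composition: ", composition_key(comp),
      "   class: ", glycan_class(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan <- function(x, ...) glycan_serialize(x)

#' @export
`==.glycan` <- function(e1, e2) {
  glycan_serialize(glycan_canonical(e1)) == glycan_serialize(glycan_canonical(e2)) &&
    is_quenched(e1) == is_quenched(e2)
}

parse_error <- function(msg, pos) {
  stop(structure(class = c("glycan_parse_error", "error", "condition"),
                 list(message = sprintf("glycan parse error at index %d: %s", pos, msg),
                      call = NULL, index = pos)))
}

# Scan one sugar token at position i; longest-match over known tokens.
.scan_sugar <- function(s, i) {
  for (tok in c("GlcNAc", "NeuAc", "Man", "Gal", "Glc", "Fuc", "Sia")) {
    n <- nchar(tok)
    if (substr(s, i, i + n - 1L) == tok) {
      sugar <- if (tok == "Sia") "NeuAc" else tok
      return(list(sugar = sugar, pos = i + n))
    }
  }
  parse_error("unknown sugar token", i)
}

.scan_linkage <- function(s, i) {
  chunk <- substr(s, i, i + 2L)
  if (!grepl("^[0-9]\\.[0-9]$", chunk)) parse_error("expected linkage code <digit>.<digit>", i)
  list(linkage = chunk, pos = i + 3L)
}

# Recursive descent over one branch chain.  A chain is a residue followed by
# either ":" (branch terminus), a linkage + chain (single continuation), or
# one or more "(linkage chain)" groups followed by "_<letter>" + linkage +
# chain (the continuation outside the brackets).
.parse_chain <- function(s, i, linkage) {
  sc <- .scan_sugar(s, i); i <- sc$pos
  node <- glycan_node(sc$sugar, linkage)
  ch <- substr(s, i, i)
  if (ch == ":") return(list(node = node, pos = i + 1L))
  saw_group <- FALSE
  while (substr(s, i, i) == "(") {
    saw_group <- TRUE
    lk <- .scan_linkage(s, i + 1L)
    sub <- .parse_chain(s, lk$pos, lk$linkage)
    i <- sub$pos
    if (substr(s, i, i) != ")") parse_error("expected ')'", i)
    i <- i + 1L
    node$children[[length(node$children) + 1L]] <- sub$node
  }
  if (saw_group) {
    if (substr(s, i, i) != "_") parse_error("expected '_' continuation after bracket group", i)
    i <- i + 1L
    if (!grepl("^[a-z]$", substr(s, i, i))) parse_error("expected lowercase continuation letter", i)
    i <- i + 1L
  }
  lk <- .scan_linkage(s, i)
  sub <- .parse_chain(s, lk$pos, lk$linkage)
  node$children[[length(node$children) + 1L]] <- sub$node
  list(node = node, pos = sub$pos)
}

#' Parse the linear glycan notation
#'
#' Reads a glycan string written root-first in the linear notation: linkage
#' codes join successive residues, brackets hold separate branches,
#' `_<letter>` resumes the chain from the residue preceding the bracket
#' group, `:` terminates a branch and `@` terminates the glycan.  Example
#' (Man5GlcNAc2):
#' `"GlcNAc4.1GlcNAc4.1Man(3.1Man:)_m6.1Man(3.1Man:)_m6.1Man:@"`.
#'
#' @param notation a single notation string.
#' @return A canonical [glycan()] object.
#' @seealso [glycan_serialize()]
#' @export
glycan_parse <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  if (!nzchar(notation)) parse_error("empty string", 1L)
  res <- .parse_chain(notation, 1L, "")
  if (substr(notation, res$pos, res$pos) != "@")
    parse_error("expected terminal '@'", res$pos)
  if (res$pos != nchar(notation))
    parse_error("trailing characters after '@'", res$pos + 1L)
  glycan_canonical(glycan(res$node))
}

.serialize_node <- function(node) {
  out <- .SUGAR_TOKENS[[node$sugar]]
  k <- length(node$children)
  if (k == 0L) return(paste0(out, ":"))
  if (k == 1L) {
    ch <- node$children[[1L]]
    return(paste0(out, ch$linkage, .serialize_node(ch)))
  }
  for (j in seq_len(k - 1L)) {
    ch <- node$children[[j]]
    out <- paste0(out, "(", ch$linkage, .serialize_node(ch), ")")
  }
  last <- node$children[[k]]
  marker <- tolower(substr(.SUGAR_TOKENS[[last$sugar]], 1L, 1L))
  paste0(out, "_", marker, last$linkage, .serialize_node(last))
}

#' Serialize a glycan to canonical linear notation
#'
#' Emits the canonical notation string for a glycan; `glycan_parse()` of the
#' result reproduces the canonical form of the input.
#'
#' @param g a [glycan()].
#' @return A notation string ending in `"@"`.
#' @export
glycan_serialize <- function(g) {
  paste0(.serialize_node(glycan_canonical(g)), "@")
}

.canonical_node <- function(node) {
  if (length(node$children) == 0L) return(node)
  kids <- lapply(node$children, .canonical_node)
  key <- vapply(kids, function(ch) paste0(ch$linkage, "", .serialize_node(ch)), "")
  node$children <- kids[order(key, method = "radix")]
  node
}

#' Canonicalize a glycan
#'
#' Sorts the children of every residue by (linkage code, canonical subtree
#' serialization) so structurally identical glycans compare equal.
#' Idempotent.
#'
#' @param g a [glycan()].
#' @return The canonical [glycan()].
#' @export
glycan_canonical <- function(g) {
  glycan(.canonical_node(unclass(g)), quenched = is_quenched(g))
}

.count_sugars <- function(node, env) {
  env$n[[node$sugar]] <- env$n[[node$sugar]] + 1L
  for (ch in node$children) .count_sugars(ch, env)
}

#' Composition of a glycan
#'
#' Counts residues by mass-spectrometric class: `Hex` (= Man + Gal),
#' `HexNAc` (= GlcNAc), `Fuc`, `NeuAc`, with `Glc` kept as its own component
#' internally (it is folded into Hex only when emitting profile keys, since
#' MS cannot distinguish Glc from other hexoses).
#'
#' @param g a [glycan()].
#' @return Named integer vector with components Fuc, NeuAc, Hex, HexNAc, Glc.
#' @export
glycan_composition <- function(g) {
  env <- new.env()
  env$n <- setNames(as.list(integer(length(.SUGARS))), .SUGARS)
  .count_sugars(unclass(g), env)
  n <- env$n
  c(Fuc = n$Fuc, NeuAc = n$NeuAc, Hex = n$Man + n$Gal, HexNAc = n$GlcNAc,
    Glc = n$Glc)
}

#' Composition key string
#'
#' Deterministic profile key in fixed component order Fuc, NeuAc, Hex,
#' HexNAc, omitting zero counts.  Glc is folded into Hex (so Man9Glc keys as
#' Hex10HexNAc2).  The key is a function of composition only and therefore
#' identical for all structural isomers.
#'
#' @param comp composition vector from [glycan_composition()], or a
#'   [glycan()] (in which case its composition is taken).
#' @return A key string such as `"Fuc1Hex3HexNAc3"`; the all-zero
#'   composition yields the sentinel `"empty"`.
#' @export
composition_key <- function(comp) {
  if (inherits(comp, "glycan")) comp <- glycan_composition(comp)
  hex <- comp[["Hex"]] + comp[["Glc"]]
  parts <- c(Fuc = comp[["Fuc"]], NeuAc = comp[["NeuAc"]], Hex = hex,
             HexNAc = comp[["HexNAc"]])
  parts <- parts[parts > 0L]
  if (length(parts) == 0L) return("empty")
  paste0(names(parts), parts, collapse = "")
}

.walk_nodes <- function(node, fun, parent = NULL, path = integer()) {
  fun(node, parent, path)
  for (j in seq_along(node$children))
    .walk_nodes(node$children[[j]], fun, node, c(path, j))
  invisible(NULL)
}

# Count of GlcNAc-initiated antennae: GlcNAc residues whose parent is a Man.
n_antennae <- function(g) {
  n <- 0L
  .walk_nodes(unclass(g), function(node, parent, path) {
    if (node$sugar == "GlcNAc" && !is.null(parent) && parent$sugar == "Man")
      n <<- n + 1L
  })
  n
}

n_sugar <- function(g, sugar) {
  n <- 0L
  .walk_nodes(unclass(g), function(node, parent, path) {
    if (node$sugar == sugar) n <<- n + 1L
  })
  n
}

#' Residue counts by sugar identity
#'
#' Counts the residues of a glycan by their chemical identity (before any
#' folding into mass-spectrometric Hex/HexNAc classes).
#'
#' @param g a [glycan()].
#' @return Named integer vector over GlcNAc, NeuAc, Man, Gal, Glc, Fuc.
#' @export
residue_counts <- function(g) {
  env <- new.env()
  env$n <- setNames(as.list(integer(length(.SUGARS))), .SUGARS)
  .count_sugars(unclass(g), env)
  vapply(.SUGARS, function(s) env$n[[s]], 0L)
}

#' Classify a glycan
#'
#' Standard N-glycan classes: `oligomannose` (five to nine mannoses, no
#' GlcNAc-initiated antenna), `hybrid` (at least one antenna and five
#' mannoses), `complex` (antennae present on the trimannosyl core, exactly
#' three mannoses).  Transient trimming intermediates that fit none of these
#' (e.g. four mannoses with an antenna) are classed `other`.
#'
#' @param g a [glycan()].
#' @return One of `"oligomannose"`, `"hybrid"`, `"complex"`, `"other"`.
#' @export
glycan_class <- function(g) {
  man <- n_sugar(g, "Man")
  ant <- n_antennae(g)
  if (ant == 0L && man >= 5L && man <= 9L) return("oligomannose")
  if (ant >= 1L && man == 5L) return("hybrid")
  if (ant >= 1L && man == 3L) return("complex")
  "other"
}

# --- reference pathway structures -----------------------------------------

# ER-exit species in linear notation.  Man9: 3-arm (A) Man carries two
# alpha-1,2 mannoses; 6-arm Man carries 3.1- and 6.1-linked mannoses, each
# capped by an alpha-1,2 mannose.  Man8 is the B-isomer (the 2.1 cap of the
# 6-arm's 3.1 branch removed).  Man9Glc carries a 3.1 Glc on the A-arm cap.
.PATHWAY_NOTATION <- c(
  Man5 = "GlcNAc4.1GlcNAc4.1Man(3.1Man:)_m6.1Man(3.1Man:)_m6.1Man:@",
  Man8 = "GlcNAc4.1GlcNAc4.1Man(3.1Man2.1Man2.1Man:)_m6.1Man(3.1Man:)_m6.1Man2.1Man:@",
  Man9 = "GlcNAc4.1GlcNAc4.1Man(3.1Man2.1Man2.1Man:)_m6.1Man(3.1Man2.1Man:)_m6.1Man2.1Man:@",
  Man9Glc = "GlcNAc4.1GlcNAc4.1Man(3.1Man2.1Man2.1Man3.1Glc:)_m6.1Man(3.1Man2.1Man:)_m6.1Man2.1Man:@"
)

#' Reference pathway glycans
#'
#' Named structures used throughout the pathway: the ER-exit species
#' (`"Man8"`, `"Man9"`, `"Man9Glc"`) and the trimmed `"Man5"`.
#'
#' @param name species name.
#' @return A [glycan()].
#' @export
pathway_glycan <- function(name) {
  if (!name %in% names(.PATHWAY_NOTATION))
    stop("unknown pathway glycan: ", name)
  glycan_parse(.PATHWAY_NOTATION[[name]])
}
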