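#' Function sets and gene geometry
#'
#' A GEP gene is a fixed-length symbol string split into a head, which may
#' hold function symbols or terminals (dataset attributes), and a tail of
#' terminals only. With `h` the head size and `n` the maximum function arity,
#' a tail of `t = h * (n - 1) + 1` symbols guarantees that breadth-first
#' (Karva) decoding always finds enough terminals to saturate every function
#' node, so every gene decodes to a valid expression tree.
#'
#' The default function set is `{+, -, /, Q}` (Q = square root), all used
#' purely structurally: trees are never evaluated numerically, they only
#' determine which attributes are expressed.
#'
#' @param symbols Named integer vector mapping function symbol to arity.
#' @return `function_set()` returns a `function_set`; `gene_shape()` a
#'   `gene_shape` with fields `head_size`, `tail_size`, `length` and `fset`.
#' @examples
#' tail_length(3, 2)   # 4
#' gene_shape(15)      # the defaults used for selection runs
#' @export
function_set <- function(symbols = c("+" = 2L, "-" = 2L, "/" = 2L, "Q" = 1L)) {
  if (is.null(names(symbols)) || any(!nzchar(names(symbols)))) {
    stop_input("function symbols must be named")
  }
  if (any(symbols < 1)) stop_input("arities must be >= 1")
  structure(list(symbols = names(symbols),
                 arity = as.integer(symbols),
                 max_arity = max(as.integer(symbols))),
            class = "function_set")
}

#' @rdname function_set
#' @param head_size Head size `h` (>= 1).
#' @param max_arity Maximum arity `n` of the function set.
#' @export
tail_length <- function(head_size, max_arity) {
  if (!is.numeric(head_size) || head_size < 1 || head_size != round(head_size)) {
    stop_input("head_size must be a positive integer")
  }
  if (!is.numeric(max_arity) || max_arity < 1 || max_arity != round(max_arity)) {
    stop_input("max_arity must be a positive integer")
  }
  as.integer(head_size * (max_arity - 1) + 1)
}

#' @rdname function_set
#' @param fset A `function_set`.
#' @param tail_size Tail size override. The default (`NULL`) recomputes the
#'   canonical `h * (n - 1) + 1`; a different value marks the shape
#'   irregular, which is only used to represent externally supplied Karva
#'   strings (e.g. truncated display strings) whose decodability is then
#'   checked explicitly.
#' @export
gene_shape <- function(head_size, fset = function_set(), tail_size = NULL) {
  t_canon <- tail_length(head_size, fset$max_arity)
  t_tail <- if (is.null(tail_size)) t_canon else as.integer(tail_size)
  if (t_tail < 1) stop_input("tail_size must be >= 1")
  structure(list(head_size = as.integer(head_size),
                 tail_size = t_tail,
                 length = as.integer(head_size) + t_tail,
                 regular = t_tail == t_canon,
                 fset = fset),
            class = "gene_shape")
}

#' @export
print.gene_shape <- function(x, ...) {
  cat(sprintf("<gene_shape> head %d + tail %d = %d symbols; functions {%s}\n",
              x$head_size, x$tail_size, x$length,
              paste(x$fset$symbols, collapse = ", ")))
  invisible(x)
}

is_function_symbol <- function(symbols, fset) symbols %in% fset$symbols

arity_of <- function(symbols, fset) {
  a <- fset$arity[match(symbols, fset$symbols)]
  a[is.na(a)] <- 0L
  a
}

new_gene <- function(symbols, shape) {
  structure(list(symbols = as.character(symbols), shape = shape), class = "gep_gene")
}

new_chromosome <- function(genes, shape) {
  structure(list(genes = genes, shape = shape, n_genes = length(genes)),
            class = "gep_chromosome")
}

#' Random genes and chromosomes
#'
#' Builds genes that satisfy the head/tail rules, drawing terminals from a
#' sampler (roulette over attribute weights in selection runs). In guided
#' mode (`root_function = TRUE`, the default) the first head position is
#' forced to a function symbol so every gene expresses more than one
#' attribute; classic GEP mode allows a terminal root. Non-root head
#' positions hold a function or a terminal with probability 1/2 each.
#'
#' @param shape A [gene_shape()].
#' @param sampler Function `f(n)` returning `n` terminal symbols.
#' @param root_function Force a function symbol at head position 0.
#' @param p_function_head Probability that a non-root head position holds a
#'   function symbol.
#' @return `random_gene()` a `gep_gene`; `random_chromosome()` a
#'   `gep_chromosome` of `n_genes` genes.
#' @export
random_gene <- function(shape, sampler, root_function = TRUE,
                        p_function_head = 0.5) {
  h <- shape$head_size
  fs <- shape$fset$symbols
  symbols <- character(shape$length)
  take_function <- runif(h) < p_function_head
  if (root_function) take_function[1] <- TRUE
  n_fun <- sum(take_function)
  if (n_fun > 0) {
    symbols[seq_len(h)][take_function] <- fs[sample.int(length(fs), n_fun, replace = TRUE)]
  }
  n_term <- h - n_fun + shape$tail_size
  terms <- sampler(n_term)
  symbols[seq_len(h)][!take_function] <- terms[seq_len(h - n_fun)]
  symbols[(h + 1L):shape$length] <- terms[(h - n_fun + 1L):n_term]
  new_gene(symbols, shape)
}

#' @rdname random_gene
#' @param n_genes Genes per chromosome.
#' @export
random_chromosome <- function(shape, n_genes, sampler, root_function = TRUE,
                              p_function_head = 0.5) {
  genes <- lapply(seq_len(n_genes), function(i) {
    random_gene(shape, sampler, root_function, p_function_head)
  })
  new_chromosome(genes, shape)
}

# Length of the expressed (breadth-first decodable) prefix of a symbol
# vector: start needing one symbol, each function claims `arity` more.
expressed_length <- function(symbols, fset) {
  need <- 1L
  i <- 0L
  ar <- arity_of(symbols, fset)
  L <- length(symbols)
  while (i < need) {
    i <- i + 1L
    if (i > L) return(need)       # > L marks an undecodable symbol string
    need <- need + ar[i]
  }
  need
}

#' Decode a gene into its expression tree
#'
#' Karva (breadth-first) decoding: symbol 0 is the root; subsequent symbols
#' fill the tree level by level, each function node claiming `arity`
#' children. Symbols beyond the expressed prefix are carried in the genotype
#' but do not appear in the tree. The head/tail geometry guarantees decoding
#' always succeeds.
#'
#' @param gene A `gep_gene`.
#' @return A nested list tree; each node has `symbol` and (for functions)
#'   `children`. The expressed prefix length is attached as attribute
#'   `n_expressed`.
#' @export
decode_expression_tree <- function(gene) {
  fset <- gene$shape$fset
  k <- expressed_length(gene$symbols, fset)
  syms <- gene$symbols[seq_len(k)]
  ar <- arity_of(syms, fset)
  # assign children breadth-first: node i takes the next `arity[i]` positions
  child_of <- vector("list", k)
  nxt <- 2L
  for (i in seq_len(k)) {
    if (ar[i] > 0) {
      child_of[[i]] <- seq.int(nxt, nxt + ar[i] - 1L)
      nxt <- nxt + ar[i]
    }
  }
  build <- function(i) {
    if (ar[i] == 0) {
      list(symbol = syms[i])
    } else {
      list(symbol = syms[i], children = lapply(child_of[[i]], build))
    }
  }
  tree <- build(1L)
  attr(tree, "n_expressed") <- k
  tree
}

format_tree <- function(node) {
  if (is.null(node$children)) return(node$symbol)
  paste0(node$symbol, "(",
         paste(vapply(node$children, format_tree, character(1)), collapse = ", "),
         ")")
}

# Expressed terminals of one gene, in breadth-first order, with multiplicity.
gene_terminals <- function(gene) {
  fset <- gene$shape$fset
  k <- expressed_length(gene$symbols, fset)
  syms <- gene$symbols[seq_len(k)]
  syms[!is_function_symbol(syms, fset)]
}

#' Attributes expressed by a chromosome
#'
#' The union over genes of the terminals reachable in each gene's decoded
#' expression tree — the candidate gene subset this chromosome stands for.
#' Unexpressed trailing symbols never contribute.
#'
#' @param chromosome A `gep_chromosome` (a single `gep_gene` is accepted).
#' @return Character vector of distinct attribute names, in first-appearance
#'   order.
#' @export
selected_attributes <- function(chromosome) {
  genes <- if (inherits(chromosome, "gep_gene")) list(chromosome) else chromosome$genes
  unique(unlist(lapply(genes, gene_terminals), use.names = FALSE))
}

#' Validate chromosome structure
#'
#' Checks the fixed-length geometry and head/tail content rules: each gene
#' has exactly `head + tail` symbols, tail positions hold terminals only, and
#' (when an attribute universe is supplied) every terminal names a known
#' attribute. Returns `TRUE` or a string describing the first violation.
#'
#' @param chromosome A `gep_chromosome`.
#' @param attributes Optional character vector of valid terminal names.
#' @param n_genes Optional expected gene count.
#' @return `TRUE`, or a character description of the first violation.
#' @export
validate_chromosome <- function(chromosome, attributes = NULL, n_genes = NULL) {
  if (!inherits(chromosome, "gep_chromosome")) return("not a gep_chromosome")
  shape <- chromosome$shape
  if (!is.null(n_genes) && length(chromosome$genes) != n_genes) {
    return(sprintf("expected %d genes, found %d", n_genes, length(chromosome$genes)))
  }
  for (gi in seq_along(chromosome$genes)) {
    g <- chromosome$genes[[gi]]
    if (length(g$symbols) != shape$length) {
      return(sprintf("gene %d has %d symbols, expected %d",
                     gi, length(g$symbols), shape$length))
    }
    is_fun <- is_function_symbol(g$symbols, shape$fset)
    tail_pos <- (shape$head_size + 1L):shape$length
    bad <- tail_pos[is_fun[tail_pos]]
    if (length(bad)) {
      return(sprintf("gene %d: function symbol '%s' at tail position %d",
                     gi, g$symbols[bad[1]], bad[1] - 1L))
    }
    if (expressed_length(g$symbols, shape$fset) > shape$length) {
      return(sprintf("gene %d: not decodable (expression exceeds gene length)", gi))
    }
    if (!is.null(attributes)) {
      terms <- g$symbols[!is_fun]
      unknown <- setdiff(terms, attributes)
      if (length(unknown)) {
        return(sprintf("gene %d: unknown terminal '%s'", gi, unknown[1]))
      }
    }
  }
  TRUE
}

#' Serialize and parse chromosomes as Karva strings
#'
#' The plain-text dialect joins genes with `" | "` and separates symbols with
#' spaces; function symbols are spelled `+ - / Q` and terminals as attribute
#' names. `parse_karva()` infers the head size from the string when `shape`
#' is `NULL` (symbol count of one gene must equal `h + h*(n-1) + 1`) and
#' validates head/tail legality. Round-trips are bit-exact.
#'
#' @param chromosome A `gep_chromosome`.
#' @return `karva_string()` a length-1 character; `parse_karva()` a
#'   `gep_chromosome`.
#' @examples
#' ch <- parse_karva("+ / Q a2 a1 a5 a6 a3")
#' selected_attributes(ch)   # a2, a1, a5
#' @export
karva_string <- function(chromosome) {
  paste(vapply(chromosome$genes, function(g) paste(g$symbols, collapse = " "),
               character(1)),
        collapse = " | ")
}

#' @rdname karva_string
#' @param x Karva string.
#' @param shape Optional [gene_shape()]; inferred when `NULL`.
#' @param fset Function set used for inference when `shape` is `NULL`.
#' @export
parse_karva <- function(x, shape = NULL, fset = function_set()) {
  gene_strs <- strsplit(x, "|", fixed = TRUE)[[1]]
  gene_syms <- lapply(gene_strs, function(s) {
    syms <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    syms[nzchar(syms)]
  })
  lens <- vapply(gene_syms, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop_input("genes differ in symbol count")
  }
  if (is.null(shape)) {
    # canonical geometry: len = h + h*(n-1) + 1  =>  h = (len - 1) / n
    n <- fset$max_arity
    h <- (lens[1] - 1) / n
    if (h >= 1 && h == round(h)) {
      shape <- gene_shape(as.integer(h), fset)
    } else {
      # irregular (e.g. truncated display) string: the head must reach the
      # last function symbol; the remainder is tail. Decodability is checked
      # by validate_chromosome() below.
      last_fun <- max(c(0L, vapply(gene_syms, function(s) {
        w <- which(is_function_symbol(s, fset))
        if (length(w)) max(w) else 0L
      }, integer(1))))
      h <- max(last_fun, 1L)
      if (h >= lens[1]) stop_input("gene has no tail symbols")
      shape <- gene_shape(h, fset, tail_size = lens[1] - h)
    }
  } else if (lens[1] != shape$length) {
    stop_input(sprintf("gene has %d symbols, shape expects %d", lens[1], shape$length))
  }
  ch <- new_chromosome(lapply(gene_syms, new_gene, shape = shape), shape)
  ok <- validate_chromosome(ch)
  if (!isTRUE(ok)) stop_input(ok)
  ch
}

#' @export
print.gep_chromosome <- function(x, ...) {
  cat("<gep_chromosome>", karva_string(x), "\n")
  cat(" expressed:", paste(selected_attributes(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gep_gene <- function(x, ...) {
  cat("<gep_gene>", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}
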