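#' Gene panel
#'
#' A named, ordered set of unique gene symbols.
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols; must be unique and, unless
#'   `allow_empty`, non-empty.
#' @param allow_empty Permit an empty panel (used for derived gene sets such
#'   as PC1-correlation selections that may legitimately be empty).
#' @return An object of class `gene_panel`: list with `name` and `genes`.
#' @export
gene_panel <- function(name, genes, allow_empty = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("panel name must be a non-empty string")
  genes <- as.character(genes)
  if (!allow_empty && length(genes) == 0L)
    stop("gene panel '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in panel '", name, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Read a gene panel from a text file
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the file.
#' @param name Panel name; defaults to the file name.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  gene_panel(name, lines[nzchar(lines)])
}

#' The 38-gene EMT transcription-factor panel
#'
#' Five core EMT transcription factors (TWIST1, SNAI1, SNAI2, ZEB1, ZEB2)
#' plus 33 EMT-related transcription factors, following the international
#' consensus nomenclature for the EMT program. This is the default panel for
#' [emt_index()].
#'
#' @return A [gene_panel()] named `"EMT38"` with 38 genes.
#' @export
emt38_panel <- function() {
  gene_panel("EMT38", c(
    # core EMT-TFs
    "TWIST1", "SNAI1", "SNAI2", "ZEB1", "ZEB2",
    # EMT-related TFs
    "KLF4", "GSC", "TCF7L2", "ALX1", "GATA6", "RUNX2", "TCF3", "SOX4",
    "FOXC2", "NFKB1", "KLF2", "KLF6", "TBX3", "TCF4", "PRRX1", "HOXB7",
    "JUN", "FOS", "TAZ", "TGIF1", "ATF1", "ERG", "ETS1", "ID1", "TEAD1",
    "YAP1", "NFYA", "KLF8", "SOX9", "SIX1", "TBXT", "GATA4", "TWIST2"))
}

#' A default 30-gene homologous recombination repair panel
#'
#' Canonical HRR pathway members: the BRCA1/2 axis, the ATM/ATR checkpoint
#' kinases, the Fanconi anemia core genes and the RAD51 paralog/remodeler
#' family. This default is a documented, replaceable stand-in — studies using
#' a bespoke HRR list should pass their own [gene_panel()] wherever `HRR30`
#' is accepted.
#'
#' @return A [gene_panel()] named `"HRR30"` with 30 genes.
#' @export
hrr30_panel <- function() {
  gene_panel("HRR30", c(
    "BRCA1", "BRCA2", "ATR", "ATRX", "ATM",
    "FANCA", "FANCB", "FANCC", "FANCD2", "FANCE", "FANCF", "FANCG",
    "FANCI", "FANCL", "FANCM",
    "RAD50", "RAD51", "RAD51B", "RAD51C", "RAD51D", "RAD52", "RAD54B",
    "RAD54L",
    "PALB2", "BARD1", "BRIP1", "CHEK1", "CHEK2", "NBN", "MRE11"))
}

# Intersect a panel with the genes of a matrix. Symbol matching is exact and
# case-sensitive; missing genes are reported (warning, or error when strict).
match_panel <- function(m, panel, strict = FALSE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(panel, "gene_panel"))
  present <- panel$genes %in% exm_genes(m)
  if (any(!present)) {
    msg <- paste0("panel '", panel$name, "': ", sum(!present),
                  " gene(s) not in matrix: ",
                  paste(panel$genes[!present], collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  if (!any(present))
    stop("no genes of panel '", panel$name, "' found in the matrix")
  panel$genes[present]
}
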