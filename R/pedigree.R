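#' Construct a validated pedigree
#'
#' A pedigree is a table of animal/sire/dam identity triplets. Animals whose
#' parents are both unknown are founders and are assumed unrelated and
#' non-inbred. Construction validates referential integrity (every named
#' parent must itself be an animal record, unless \code{auto_add_founders}),
#' checks for duplicate ids and parentage cycles, and reorders the records
#' into a stable topological order in which every parent precedes all of its
#' offspring; among unconstrained records the input order is preserved so
#' that downstream matrices are reproducible.
#'
#' @param animal,sire,dam character vectors of equal length; unknown parents
#'   are \code{NA} or one of \code{missing_tokens}.
#' @param missing_tokens values (besides \code{NA}) that denote an unknown
#'   parent; defaults to \code{c("0", "", "NA")}.
#' @param auto_add_founders if \code{TRUE}, parents referenced but never
#'   listed as animals are prepended as founder records instead of raising
#'   an error.
#' @return An object of class \code{"pedigree"}: a data.frame with columns
#'   \code{animal}, \code{sire}, \code{dam} (character; \code{NA} = unknown)
#'   in topological order, plus integer columns \code{sire_idx},
#'   \code{dam_idx} (0 = unknown) giving parent positions in that order.
#' @seealso [read_pedigree()], [additive_relationship()]
#' @export
pedigree <- function(animal, sire, dam, missing_tokens = c("0", "", "NA"),
                     auto_add_founders = FALSE) {
  animal <- as.character(animal)
  sire <- clean_parent(sire, missing_tokens)
  dam <- clean_parent(dam, missing_tokens)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (anyNA(animal) || any(animal %in% missing_tokens))
    stop("animal ids may not be missing")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))

  referenced <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(referenced)) {
    if (!auto_add_founders)
      stop("parent id(s) never defined as animals: ",
           paste(referenced, collapse = ", "),
           " (set auto_add_founders = TRUE to add them as founders)")
    animal <- c(referenced, animal)
    sire <- c(rep(NA_character_, length(referenced)), sire)
    dam <- c(rep(NA_character_, length(referenced)), dam)
  }

  ord <- topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  ped$sire_idx <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  ped$dam_idx <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  class(ped) <- c("pedigree", "data.frame")
  ped
}

clean_parent <- function(x, missing_tokens) {
  x <- as.character(x)
  x[x %in% missing_tokens] <- NA_character_
  x
}

# Kahn topological sort, stable in input order among free records.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  pos <- seq_len(n)
  names(pos) <- animal
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L)     # ascending = input order
  while (length(ready)) {
    i <- ready[1]
    ready <- ready[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- sort(c(ready, k))
    }
  }
  if (length(out) < n)
    stop("pedigree contains a parentage cycle involving: ",
         paste(animal[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header. Columns are picked out by name through
#' \code{columns}, so extra columns are ignored.
#'
#' @param path path to a CSV or TSV file.
#' @param sep field separator; by default inferred from the file extension
#'   (\code{.tsv}/\code{.txt} tab, otherwise comma).
#' @param columns length-3 character vector naming the animal, sire and dam
#'   columns in the file.
#' @inheritParams pedigree
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, sep = NULL,
                          columns = c("animal", "sire", "dam"),
                          missing_tokens = c("0", "", "NA"),
                          auto_add_founders = FALSE) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols))
    stop("pedigree file lacks column(s): ", paste(missing_cols, collapse = ", "))
  pedigree(tab[[columns[1]]], tab[[columns[2]]], tab[[columns[3]]],
           missing_tokens = missing_tokens,
           auto_add_founders = auto_add_founders)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire_idx == 0L & x$dam_idx == 0L)
  cat(sprintf("Pedigree: %d animals (%d founders, %d non-founders)\n",
              nrow(x), nf, nrow(x) - nf))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Founder animals of a pedigree
#'
#' @param ped a [pedigree()] object.
#' @return character vector of animal ids with both parents unknown.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$animal[ped$sire_idx == 0L & ped$dam_idx == 0L]
}

#' Additive (numerator) relationship matrix
#'
#' Builds the matrix A of expected additive genetic relationships (twice the
#' kinship coefficients) by the tabular method, processing animals in
#' pedigree order: for animal i with parents s and d already processed,
#' \eqn{A_{ij} = (A_{js} + A_{jd})/2} for every earlier j and
#' \eqn{A_{ii} = 1 + A_{sd}/2}; unknown parents contribute 0. A enters the
#' animal model as the correlation structure of the additive genetic
#' effects, \eqn{var(a) = V_A A}.
#'
#' @param ped a [pedigree()] object.
#' @return A symmetric dense matrix with dimnames equal to the animal ids in
#'   pedigree order, carrying a per-animal inbreeding coefficient
#'   \eqn{F_i = A_{ii} - 1} in attribute \code{"inbreeding"}.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  si <- ped$sire_idx
  di <- ped$dam_idx
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (max(s, d) >= i)
      stop("pedigree is not topologically ordered at animal ", ped$animal[i])
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0L) v <- v + A[prev, s]
      if (d > 0L) v <- v + A[prev, d]
      v <- v / 2
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  attr(A, "inbreeding") <- stats::setNames(diag(A) - 1, ped$animal)
  A
}

#' Pairwise additive relationship by direct recursion
#'
#' Computes a single coefficient of the numerator relationship matrix by
#' recursing on the pair of animals (memoised, but without ever forming the
#' tabular matrix). Kept deliberately independent of
#' [additive_relationship()] so the two can cross-check each other.
#'
#' @param ped a [pedigree()] object.
#' @param i,j animal ids.
#' @return the additive relationship \eqn{A_{ij}}.
#' @export
relationship_coefficient <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  for (id in c(i, j))
    if (!id %in% ped$animal) stop("unknown animal id: ", id)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  si <- ped$sire_idx
  di <- ped$dam_idx
  rec <- function(x, y) {
    if (x == 0L || y == 0L) return(0)
    if (x < y) { tmp <- x; x <- y; y <- tmp }   # x is the later-born
    key <- paste0(x, ":", y)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (x == y) {
      1 + rec(si[x], di[x]) / 2
    } else {
      (rec(si[x], y) + rec(di[x], y)) / 2
    }
    memo[[key]] <- v
    v
  }
  rec(pos[[i]], pos[[j]])
}

#' Write a relationship matrix as TSV
#'
#' Emits a tab-separated table with a header row and a leading column of
#' animal labels, for inspection and for exchange with other tools.
#'
#' @param A matrix from [additive_relationship()].
#' @param path output file path.
#' @export
write_relationship <- function(A, path) {
  df <- data.frame(animal = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
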