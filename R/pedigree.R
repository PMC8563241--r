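#' Pedigree objects
#'
#' A `kr_pedigree` is a validated data frame of animal records with columns
#' `animal`, `sire`, `dam` (parent ids or `NA` for unknown) and optional
#' `line`, `sex`, `hatch`, `generation`. Invariants enforced at construction:
#' unique animal ids, no animal is its own ancestor, and every non-missing
#' parent id refers to a record in the pedigree.
#'
#' @param df data frame with at least columns `animal`, `sire`, `dam`.
#' @param add_missing_founders if `TRUE`, parents that are referenced but have
#'   no record of their own are prepended as founder records (unknown
#'   parents, line/sex/hatch `NA`). The default rejects them so that data
#'   errors surface instead of being silently absorbed.
#' @return an object of class `kr_pedigree`.
#' @export
as_pedigree <- function(df, add_missing_founders = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("animal", "sire", "dam")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pedigree is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  clean_id <- function(x) {
    x <- trimws(as.character(x))
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  df$animal <- clean_id(df$animal)
  df$sire   <- clean_id(df$sire)
  df$dam    <- clean_id(df$dam)

  if (anyNA(df$animal)) stop("pedigree contains missing animal ids")
  dup <- unique(df$animal[duplicated(df$animal)])
  if (length(dup))
    stop("duplicated animal id(s): ", paste(utils::head(dup, 5), collapse = ", "))

  parents <- unique(stats::na.omit(c(df$sire, df$dam)))
  absent <- setdiff(parents, df$animal)
  if (length(absent)) {
    if (!add_missing_founders)
      stop("parent id(s) not present as records: ",
           paste(utils::head(absent, 5), collapse = ", "),
           " (use add_missing_founders = TRUE to auto-create founders)")
    founders <- df[rep.int(NA_integer_, length(absent)), , drop = FALSE]
    founders$animal <- absent
    founders$sire <- NA_character_
    founders$dam <- NA_character_
    if ("generation" %in% names(founders)) founders$generation <- 0L
    df <- rbind(founders, df)
    rownames(df) <- NULL
  }

  for (col in c("line", "sex", "hatch")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  if (!"generation" %in% names(df)) df$generation <- NA_integer_

  ped <- structure(
    df[c("animal", "sire", "dam", "line", "sex", "hatch", "generation")],
    class = c("kr_pedigree", "data.frame")
  )
  assert_acyclic(ped)
  ped
}

#' Read a pedigree CSV
#'
#' Expected columns `animal,sire,dam` plus optional `line,sex,hatch,generation`;
#' unknown parents encoded as an empty field or `0`. Column names can be
#' remapped through `dialect`, e.g. `c(animal = "id", sire = "father")`.
#'
#' @param path path to a CSV file with a header row (UTF-8).
#' @param dialect named character vector mapping canonical column names to the
#'   names used in the file.
#' @inheritParams as_pedigree
#' @return a `kr_pedigree`.
#' @export
read_pedigree <- function(path, dialect = NULL, add_missing_founders = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df))
        stop("dialect column '", dialect[[canon]], "' not found in ", path)
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  as_pedigree(df, add_missing_founders = add_missing_founders)
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as empty fields, matching [read_pedigree()].
#'
#' @param ped a `kr_pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "kr_pedigree"))
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Detect self-ancestry; reports one offending cycle by id path.
assert_acyclic <- function(ped) {
  ord <- try(topological_index(ped), silent = TRUE)
  if (!inherits(ord, "try-error")) return(invisible(TRUE))
  # find and name a cycle by walking parent links from a node that never
  # became placeable
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  # At a stall every stuck record has at least one parent that is itself
  # stuck, so walking parent links inside the stuck set must close a cycle.
  stuck <- attr(ord, "condition")$kradom_stuck %||% seq_along(ids)
  path <- integer(0)
  i <- stuck[[1]]
  seen <- logical(length(ids))
  while (!seen[i]) {
    seen[i] <- TRUE
    path <- c(path, i)
    nxt <- intersect(c(si[i], di[i]), stuck)
    i <- nxt[[1]]
  }
  cyc <- path[which(path == i)[1]:length(path)]
  stop("pedigree contains a cycle: ",
       paste(ids[c(cyc, cyc[1])], collapse = " -> "))
}

# Stable topological order of record indices: repeatedly place the earliest
# (by input position) record whose parents are already placed. A pedigree
# that is already validly ordered is therefore returned unchanged.
topological_index <- function(ped) {
  ids <- ped$animal
  q <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  n_unplaced_parents <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", q)
  for (i in seq_len(q)) {
    for (p in unique(stats::na.omit(c(si[i], di[i]))))
      children[[p]] <- c(children[[p]], i)
  }
  placed <- logical(q)
  eligible <- n_unplaced_parents == 0L
  ord <- integer(q)
  for (k in seq_len(q)) {
    i <- which(eligible & !placed)[1]
    if (is.na(i)) {
      cond <- simpleError("cycle detected")
      cond$kradom_stuck <- which(!placed)
      stop(cond)
    }
    ord[k] <- i
    placed[i] <- TRUE
    for (ch in children[[i]]) {
      n_unplaced_parents[ch] <- n_unplaced_parents[ch] -
        sum(c(si[ch], di[ch]) == i, na.rm = TRUE)
      if (n_unplaced_parents[ch] == 0L) eligible[ch] <- TRUE
    }
  }
  ord
}

#' Topologically order a pedigree
#'
#' Reorders records so that every parent precedes all of its offspring. The
#' ordering is stable: among records whose parents are already placed, input
#' order is preserved, so an already-ordered pedigree is returned unchanged.
#'
#' @param ped a `kr_pedigree`.
#' @return the reordered `kr_pedigree`.
#' @export
topological_order <- function(ped) {
  stopifnot(inherits(ped, "kr_pedigree"))
  ord <- tryCatch(topological_index(ped),
                  error = function(e) stop("pedigree contains a cycle"))
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_topologically_ordered <- function(ped) {
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  pos <- seq_along(ids)
  !(any(si >= pos, na.rm = TRUE) || any(di >= pos, na.rm = TRUE))
}

new_relmat <- function(values, kind) {
  structure(values, kind = kind, class = c("kr_relmat", class(values)))
}

#' @export
print.kr_relmat <- function(x, ...) {
  cat(sprintf("<%s relationship matrix, %d animals>\n",
              attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' Numerator (additive) relationship matrix
#'
#' Computes A by the tabular method on a topologically ordered pedigree:
#' `a_ii = 1 + 0.5 * a(sire_i, dam_i)` and, for j earlier than i,
#' `a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i))`, with unknown-parent terms
#' contributing zero. Founders are taken as unrelated and non-inbred, so the
#' diagonal is `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped a topologically ordered `kr_pedigree`.
#' @return a `kr_relmat` of kind `"additive"` with animal ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "kr_pedigree"))
  if (!is_topologically_ordered(ped))
    stop("pedigree is not topologically ordered; call topological_order() first")
  ids <- ped$animal
  q <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, q, q, dimnames = list(ids, ids))
  for (i in seq_len(q)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + A[j, s]
      if (!is.na(d)) v <- v + A[j, d]
      v <- 0.5 * v
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  new_relmat(A, "additive")
}

#' Dominance relationship matrix
#'
#' For animals i and j with both parents known,
#' `d_ij = 0.25 * (a(s_i,s_j) a(d_i,d_j) + a(s_i,d_j) a(d_i,s_j))` from the
#' additive matrix of the same pedigree; the diagonal is fixed at 1 and any
#' animal with an unknown parent has zero off-diagonal dominance relationship
#' (classical non-inbred dominance relationship; inbreeding is ignored in D).
#'
#' @param ped a topologically ordered `kr_pedigree`.
#' @param A the additive relationship matrix of `ped`.
#' @return a `kr_relmat` of kind `"dominance"`.
#' @export
dominance_relationship_matrix <- function(ped, A) {
  stopifnot(inherits(ped, "kr_pedigree"))
  ids <- ped$animal
  q <- length(ids)
  if (nrow(A) != q || is.null(rownames(A)) || !identical(rownames(A), ids))
    stop("A does not match the pedigree (dimension or animal ids differ)")
  Av <- unclass(A)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  D <- matrix(0, q, q, dimnames = list(ids, ids))
  k <- which(!is.na(si) & !is.na(di))
  if (length(k)) {
    S <- si[k]; Dm <- di[k]
    D[k, k] <- 0.25 * (Av[S, S, drop = FALSE] * Av[Dm, Dm, drop = FALSE] +
                       Av[S, Dm, drop = FALSE] * Av[Dm, S, drop = FALSE])
  }
  diag(D) <- 1
  new_relmat(D, "dominance")
}

#' Export a relationship matrix as lower-triangle triplets
#'
#' Writes a whitespace-free CSV of `(row_id,col_id,value)` for the lower
#' triangle (including the diagonal).
#'
#' @param m a `kr_relmat` (or square symmetric matrix with dimnames).
#' @param path output path.
#' @param drop_zero omit exact-zero entries (default `TRUE`).
#' @export
write_relmat_triplets <- function(m, path, drop_zero = TRUE) {
  ids <- rownames(m)
  idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  val <- m[idx]
  if (drop_zero) {
    keep <- val != 0
    idx <- idx[keep, , drop = FALSE]
    val <- val[keep]
  }
  out <- data.frame(row_id = ids[idx[, 1]], col_id = ids[idx[, 2]],
                    value = val, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
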