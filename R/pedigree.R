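#' Pedigree construction and validation
#'
#' A pedigree is a data frame with character columns `animal`, `sire`, `dam`
#' (NA = unknown parent) sorted so that parents always precede offspring.
#' Parents referenced but not listed as animals are added as founders.
#'
#' @param animal character vector of animal ids (unique).
#' @param sire,dam character vectors of parent ids; `NA`, `""` or `"0"` mean
#'   unknown.
#' @param sex optional character/factor vector ("M"/"F") carried along.
#' @return a `pedigree` object (data frame `animal`, `sire`, `dam`, optional
#'   `sex`, topologically ordered).
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' @export
pedigree <- function(animal, sire = NA, dam = NA, sex = NULL) {
  animal <- as.character(animal)
  sire <- clean_parent(rep_len(as.character(sire), length(animal)))
  dam <- clean_parent(rep_len(as.character(dam), length(animal)))
  if (anyDuplicated(animal))
    stopf("duplicated animal ids: %s",
          paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (any(animal == sire, na.rm = TRUE) || any(animal == dam, na.rm = TRUE))
    stopf("an animal is recorded as its own parent")
  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- as.character(rep_len(sex, length(animal)))
  # add referenced-but-unlisted parents as founders
  refs <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(refs)) {
    add <- data.frame(animal = refs, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(df$sex)) add$sex <- NA_character_
    df <- rbind(add, df)
  }
  df <- topo_sort_pedigree(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

clean_parent <- function(x) {
  x[x %in% c("", "0", "NA", ".")] <- NA_character_
  x
}

# Kahn's algorithm; errors on cycles.
topo_sort_pedigree <- function(df) {
  n <- nrow(df)
  id <- df$animal
  si <- match(df$sire, id)
  di <- match(df$dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(si[j], di[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        children[[p]] <- c(children[[p]], j)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # keep input order among ready nodes for stable output
    j <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, j)
    for (ch in children[[j]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stopf("pedigree contains a cycle involving: %s",
          paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  df[ord, , drop = FALSE]
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d animals (%d founders)\n", nrow(x), founders))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read / write a pedigree as TSV
#'
#' Expected columns `animal`, `sire`, `dam` (extra columns kept); `0`, `NA`
#' or empty mean unknown parent.
#' @param path file path.
#' @return `read_pedigree` returns a [pedigree()]; `write_pedigree` writes
#'   `ped` to `path` (unknown parents as 0) and returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stopf("pedigree file must have columns: %s", paste(need, collapse = ", "))
  pedigree(df$animal, df$sire, df$dam, sex = df$sex)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parent_index <- function(ped) {
  list(sire = match(ped$sire, ped$animal),
       dam = match(ped$dam, ped$animal))
}
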