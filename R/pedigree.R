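#' Construct a pedigree with analysis roles
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sire`, `dam`, `sex` and `role`. Founders have `NA` parents.
#' Roles drive the downstream mapping criteria: `case` individuals must be
#' autozygous for the causal haplotype, `obligate_carrier` individuals
#' (e.g. dams of affected offspring) must carry exactly one copy, `control`
#' individuals must never be homozygous for it, and `unknown` individuals
#' are carried along but unconstrained.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam identifiers of the parents (`NA` for founders). Every
#'   named sire must be a male in the pedigree and every dam a female.
#' @param sex `"M"` or `"F"` per individual.
#' @param role one of `"case"`, `"obligate_carrier"`, `"control"`,
#'   `"unknown"` per individual.
#' @return An object of class `pedigree` (a data frame).
#' @examples
#' pedigree(id = c("p", "m", "o"), sire = c(NA, NA, "p"),
#'          dam = c(NA, NA, "m"), sex = c("M", "F", "F"),
#'          role = c("unknown", "obligate_carrier", "case"))
#' @export
pedigree <- function(id, sire, dam, sex, role = "unknown") {
  df <- data.frame(
    id = as.character(id),
    sire = as.character(sire),
    dam = as.character(dam),
    sex = as.character(sex),
    role = rep_len(as.character(role), length(id)),
    stringsAsFactors = FALSE
  )
  validate_pedigree(df)
}

validate_pedigree <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("id", "sire", "dam", "sex", "role") %in% names(df)))
  if (anyDuplicated(df$id))
    stop("duplicated individual ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  roles <- c("case", "obligate_carrier", "control", "unknown")
  if (!all(df$role %in% roles))
    stop("role must be one of: ", paste(roles, collapse = ", "))
  for (p in c("sire", "dam")) {
    named <- !is.na(df[[p]])
    missing_parent <- setdiff(df[[p]][named], df$id)
    if (length(missing_parent))
      stop(p, "(s) not present in pedigree: ",
           paste(missing_parent, collapse = ", "))
    want_sex <- if (p == "sire") "M" else "F"
    bad <- df[[p]][named][df$sex[match(df[[p]][named], df$id)] != want_sex]
    if (length(bad))
      stop(p, "(s) with wrong sex: ", paste(unique(bad), collapse = ", "))
  }
  # acyclicity via topological sort (errors if a cycle exists)
  topo_order(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Topological order of a pedigree (parents before offspring)
#'
#' @param ped a [pedigree()].
#' @return Character vector of ids, every parent preceding its offspring.
#' @export
topo_order <- function(ped) {
  ids <- ped$id
  placed <- character(0)
  remaining <- ids
  while (length(remaining)) {
    sire <- ped$sire[match(remaining, ped$id)]
    dam <- ped$dam[match(remaining, ped$id)]
    ready <- (is.na(sire) | sire %in% placed) &
      (is.na(dam) | dam %in% placed)
    if (!any(ready))
      stop("pedigree contains a cycle involving: ",
           paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Founders of a pedigree
#' @param ped a [pedigree()].
#' @return ids of individuals with both parents unknown.
#' @export
founders <- function(ped) ped$id[is.na(ped$sire) & is.na(ped$dam)]

#' All ancestors of an individual
#' @param ped a [pedigree()].
#' @param id individual identifier.
#' @return Character vector of ancestor ids (excluding `id` itself).
#' @export
ancestors <- function(ped, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    i <- match(frontier, ped$id)
    parents <- stats::na.omit(c(ped$sire[i], ped$dam[i]))
    parents <- setdiff(parents, out)
    out <- c(out, parents)
    frontier <- parents
  }
  unique(out)
}

#' Default study pedigree: half-sib matings descending from one carrier bull
#'
#' Builds the pedigree structure the simulator emulates: a single ancestral
#' carrier bull (`B1`) whose son (`S1`) sired two affected calves out of two
#' of B1's daughters (half-sib matings), the two dams as obligate carriers,
#' four further heterozygous relatives, four unaffected close relatives, the
#' carrier bull's non-carrier sire, and a sample of unrelated population
#' controls standing in for the breed reference animals used in mapping.
#'
#' @param n_population number of unrelated control founders appended to the
#'   family (default 30).
#' @return A [pedigree()].
#' @export
build_default_pedigree <- function(n_population = 30) {
  id <- c("BS", "BD", paste0("FM", 1:8), "US1", "US2",
          "B1", "S1", "D1", "D2", "R1", "R2", "R3", "R4",
          "C1", "C2", "C3", "C4", "A1", "A2")
  sire <- c(rep(NA, 12),
            "BS", "B1", "B1", "B1", "B1", "B1", "S1", "S1",
            "US1", "US1", "US2", "US2", "S1", "S1")
  dam <- c(rep(NA, 12),
           "BD", "FM1", "FM2", "FM3", "FM4", "FM5", "FM6", "FM7",
           "FM2", "FM3", "FM4", "FM8", "D1", "D2")
  sex <- c("M", "F", rep("F", 8), "M", "M",
           "M", "M", "F", "F", "F", "M", "F", "M",
           "M", "F", "M", "F", "M", "F")
  role <- c("control", "unknown", rep("unknown", 8), "control", "control",
            "obligate_carrier", "obligate_carrier", "obligate_carrier",
            "obligate_carrier", "obligate_carrier", "obligate_carrier",
            "obligate_carrier", "obligate_carrier",
            "control", "control", "control", "control", "case", "case")
  if (n_population > 0) {
    pid <- sprintf("UP%02d", seq_len(n_population))
    id <- c(id, pid)
    sire <- c(sire, rep(NA, n_population))
    dam <- c(dam, rep(NA, n_population))
    sex <- c(sex, rep(c("M", "F"), length.out = n_population))
    role <- c(role, rep("control", n_population))
  }
  pedigree(id, sire, dam, sex, role)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  cat("Roles:", paste(sprintf("%s=%d", names(table(x$role)),
                              as.integer(table(x$role))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Named role vector of a pedigree
#' @param ped a [pedigree()].
#' @return Named character vector, sample id -> role.
#' @export
pedigree_roles <- function(ped) stats::setNames(ped$role, ped$id)
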