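#' Load a term inventory
#'
#' A term inventory maps normalized search terms and synonyms to outlet
#' categories. It drives both the grid query (which terms are searched)
#' and the classifier (which terms are looked for in establishment names
#' and provider type labels). The package ships a Spanish-language
#' default covering the eight categories; it is fully user-replaceable.
#'
#' @param path CSV file with columns \code{term}, \code{category},
#'   \code{match_kind} (one of \code{name}, \code{provider_type},
#'   \code{both}) and integer \code{priority} (larger = matched first).
#'   \code{NULL} loads the shipped default.
#' @return data.frame of class \code{term_inventory} with an extra
#'   \code{term_norm} column (accent-folded, lowercased).
#' @export
read_term_inventory <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "term_inventory.csv", package = "foodenv")
  inv <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("term", "category", "match_kind", "priority")
  miss <- setdiff(need, names(inv))
  if (length(miss))
    stop("term inventory missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(inv$category), food_categories())
  if (length(bad))
    stop("term inventory has unknown categories: ", paste(bad, collapse = ", "))
  if (!all(inv$match_kind %in% c("name", "provider_type", "both")))
    stop("match_kind must be one of name, provider_type, both")
  inv$term_norm <- normalize_name(inv$term)
  for (kind in c("name", "provider_type")) {
    sub <- inv$term_norm[inv$match_kind %in% c(kind, "both")]
    if (anyDuplicated(sub))
      stop("duplicate ", kind, " terms after normalization: ",
           paste(unique(sub[duplicated(sub)]), collapse = ", "))
  }
  class(inv) <- c("term_inventory", "data.frame")
  inv
}

# terms that may match names, in match precedence order:
# priority desc, then longer term, then lexicographic
.name_terms <- function(inventory) {
  nm <- inventory[inventory$match_kind %in% c("name", "both"), ]
  nm[order(-nm$priority, -nchar(nm$term_norm), nm$term_norm), ]
}

.type_terms <- function(inventory) {
  ty <- inventory[inventory$match_kind %in% c("provider_type", "both"), ]
  ty[order(-ty$priority, -nchar(ty$term_norm), ty$term_norm), ]
}

#' Classify establishments into outlet categories
#'
#' Name-first hierarchy: (1) the normalized name is scanned for inventory
#' terms on word boundaries; the highest-priority hit wins, ties broken
#' by longest term then lexicographic order. (2) If the name carries no
#' inventory term, the provider's primary and then secondary type labels
#' are matched against \code{provider_type} inventory entries. (3)
#' Otherwise the establishment is \code{unclassified}. The decision path
#' is recorded for every record.
#'
#' @param establishments data.frame with columns \code{name},
#'   \code{primary_type}, and optionally \code{secondary_types}
#'   (semicolon-separated labels).
#' @param inventory a \code{\link{read_term_inventory}} inventory.
#' @return the input with added columns \code{category},
#'   \code{health_group} (\code{NA} when unclassified) and
#'   \code{match_path} (\code{"name"}, \code{"provider_primary"},
#'   \code{"provider_secondary"} or \code{"none"}).
#' @export
classify_establishments <- function(establishments, inventory = read_term_inventory()) {
  stopifnot(is.data.frame(establishments))
  if (!nrow(establishments)) {
    establishments$category <- character(0)
    establishments$health_group <- character(0)
    establishments$match_path <- character(0)
    return(establishments)
  }
  if (!all(c("name", "primary_type") %in% names(establishments)))
    stop("establishments need columns 'name' and 'primary_type'")
  if (is.null(establishments$secondary_types))
    establishments$secondary_types <- ""

  n <- nrow(establishments)
  category <- rep("unclassified", n)
  path <- rep("none", n)

  # step 1: name terms, one vectorized word-boundary grepl per term,
  # terms visited in precedence order so the first hit wins
  nm_norm <- normalize_name(establishments$name)
  nmt <- .name_terms(inventory)
  open <- rep(TRUE, n)
  for (i in seq_len(nrow(nmt))) {
    if (!any(open)) break
    rx <- paste0("\\b", nmt$term_norm[i], "\\b")
    hit <- open & grepl(rx, nm_norm, perl = TRUE)
    if (any(hit)) {
      category[hit] <- nmt$category[i]
      path[hit] <- "name"
      open <- open & !hit
    }
  }

  # step 2: provider label fallback, primary before secondary
  tyt <- .type_terms(inventory)
  type_map <- stats::setNames(tyt$category, tyt$term_norm)
  if (any(open)) {
    prim <- normalize_name(establishments$primary_type)
    hit <- open & prim %in% names(type_map)
    category[hit] <- unname(type_map[prim[hit]])
    path[hit] <- "provider_primary"
    open <- open & !hit
  }
  if (any(open)) {
    for (j in which(open)) {
      sec <- normalize_name(strsplit(establishments$secondary_types[j], ";")[[1]])
      sec <- sec[nzchar(sec)]
      m <- sec[sec %in% names(type_map)]
      if (length(m)) {
        category[j] <- unname(type_map[m[1]])
        path[j] <- "provider_secondary"
      }
    }
  }

  establishments$category <- category
  establishments$health_group <- ifelse(category == "unclassified",
                                        NA_character_, unname(.health_map[category]))
  establishments$match_path <- path
  establishments
}

#' Classify a single establishment
#'
#' Scalar convenience wrapper around \code{\link{classify_establishments}}.
#'
#' @param name establishment name.
#' @param primary_type provider primary type label (may be \code{""}).
#' @param secondary_types character vector of provider secondary labels.
#' @param inventory term inventory.
#' @return the assigned category label (possibly \code{"unclassified"}).
#' @export
classify <- function(name, primary_type = "", secondary_types = character(0),
                     inventory = read_term_inventory()) {
  df <- data.frame(name = name, primary_type = primary_type,
                   secondary_types = paste(secondary_types, collapse = ";"),
                   stringsAsFactors = FALSE)
  classify_establishments(df, inventory)$category
}

#' Summarise a classified registry
#'
#' Counts and proportions per category and per health group, computed
#' over classified establishments only; the unclassified residue is
#' reported separately. Counts always satisfy the conservation identity
#' \code{sum(category counts) + unclassified = total}.
#'
#' @param establishments output of \code{\link{classify_establishments}}.
#' @return list with elements \code{by_category} (data.frame: category,
#'   n, pct of classified), \code{by_health_group}, \code{n_total},
#'   \code{n_classified}, \code{n_unclassified}, \code{pct_classified}.
#' @export
classification_summary <- function(establishments) {
  if (!nrow(establishments)) {
    warning("empty establishment set")
    return(list(by_category = data.frame(category = character(0),
                                         n = integer(0), pct = numeric(0)),
                by_health_group = data.frame(health_group = character(0),
                                             n = integer(0), pct = numeric(0)),
                n_total = 0L, n_classified = 0L, n_unclassified = 0L,
                pct_classified = NA_real_))
  }
  cat_f <- factor(establishments$category,
                  levels = c(food_categories(), "unclassified"))
  tab <- table(cat_f)
  n_total <- nrow(establishments)
  n_uncl <- as.integer(tab[["unclassified"]])
  n_class <- n_total - n_uncl
  cat_tab <- data.frame(category = food_categories(),
                        n = as.integer(tab[food_categories()]),
                        stringsAsFactors = FALSE)
  cat_tab$pct <- if (n_class > 0) 100 * cat_tab$n / n_class else NA_real_
  hg <- unname(.health_map[cat_tab$category])
  hg_tab <- stats::aggregate(cat_tab["n"], by = list(health_group = hg), FUN = sum)
  hg_tab <- hg_tab[match(health_groups(), hg_tab$health_group), ]
  rownames(hg_tab) <- NULL
  hg_tab$pct <- if (n_class > 0) 100 * hg_tab$n / n_class else NA_real_
  list(by_category = cat_tab, by_health_group = hg_tab,
       n_total = n_total, n_classified = n_class, n_unclassified = n_uncl,
       pct_classified = if (n_total > 0) 100 * n_class / n_total else NA_real_)
}

#' Build a review queue for unclassified establishments
#'
#' The unclassified residue would traditionally be resolved by manual
#' review; this emits its automatable surrogate: every unclassified
#' record together with its nearest-miss inventory term (the name term
#' with the smallest edit distance to any word in the name), so a human
#' or a later rule revision can act on it.
#'
#' @param establishments classified establishment data.frame.
#' @param inventory term inventory.
#' @return data.frame of unclassified records with columns
#'   \code{nearest_term} and \code{nearest_distance} appended.
#' @export
review_queue <- function(establishments, inventory = read_term_inventory()) {
  q <- establishments[establishments$category == "unclassified", , drop = FALSE]
  if (!nrow(q)) {
    q$nearest_term <- character(0)
    q$nearest_distance <- integer(0)
    return(q)
  }
  terms <- .name_terms(inventory)$term_norm
  nearest <- t(vapply(normalize_name(q$name), function(nm) {
    words <- strsplit(nm, " ")[[1]]
    if (!length(words)) return(c(NA, NA))
    d <- utils::adist(words, terms)
    k <- arrayInd(which.min(d), dim(d))
    c(k[2], min(d))
  }, numeric(2)))
  q$nearest_term <- ifelse(is.na(nearest[, 1]), NA_character_, terms[nearest[, 1]])
  q$nearest_distance <- nearest[, 2]
  rownames(q) <- NULL
  q
}
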