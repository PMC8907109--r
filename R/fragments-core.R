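## Vectorized internals shared by the fragment enumerators.  Fragments are
## assembled as rows of an element-count matrix (columns = elements), so a
## whole series is computed with matrix arithmetic and converted to
## formula strings and masses in one pass.

counts_vec <- function(f, elements) {
  v <- setNames(numeric(length(elements)), elements)
  v[names(f)] <- as.numeric(f)
  v
}

## Hill-style strings for every row of an element-count matrix
formula_strings <- function(mat, elements) {
  if (!nrow(mat)) return(character(0))
  if (any(mat < 0))
    abort("negative element count in fragment formula")
  ord <- order(match(elements, c("C", "H"), nomatch = 3L), elements)
  mat <- mat[, ord, drop = FALSE]
  els <- elements[ord]
  parts <- lapply(seq_along(els), function(j) {
    cnt <- mat[, j]
    ifelse(cnt == 0, "", paste0(els[j], ifelse(cnt == 1, "", cnt)))
  })
  do.call(paste0, parts)
}

## assemble the standard fragment tibble from parallel vectors + count rows
fragment_tbl <- function(polymer, kind, series5, series3, index, start, end,
                         base_loss_pos, base_loss, label, mat, elements) {
  n <- nrow(mat)
  tibble::new_tibble(list(
    polymer = rep_len(polymer, n), kind = rep_len(kind, n),
    series5 = rep_len(series5, n), series3 = rep_len(series3, n),
    index = rep_len(as.integer(index), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    base_loss_pos = rep_len(as.integer(base_loss_pos), n),
    base_loss = rep_len(if (is.null(base_loss)) NA_character_ else
      as.character(base_loss), n),
    neutral_loss = rep_len(NA_character_, n),
    label = rep_len(label, n),
    formula = formula_strings(mat, elements),
    neutral_mass = as.numeric(mat %*% principal_masses()[elements])),
    nrow = n)
}

empty_fragments <- function() {
  tibble(polymer = character(), kind = character(),
         series5 = character(), series3 = character(), index = integer(),
         start = integer(), end = integer(),
         base_loss_pos = integer(), base_loss = character(),
         neutral_loss = character(), label = character(),
         formula = character(), neutral_mass = numeric())
}

apply_neutral_losses <- function(rows, neutral_losses) {
  if (is.null(neutral_losses) || !length(neutral_losses) || !nrow(rows))
    return(rows)
  extra <- purrr::map_dfr(neutral_losses, function(nl) {
    d <- as_formula(nl)
    out <- rows
    out$neutral_loss <- nl
    out$label <- paste0(out$label, "-", nl)
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      f <- fml_subtract(parse_formula(out$formula[i]), d)
      if (all(f >= 0L)) {
        keep[i] <- TRUE
        out$formula[i] <- formula_string(f)
        out$neutral_mass[i] <- monoisotopic_mass(f)
      }
    }
    out[keep, ]
  })
  dplyr::bind_rows(rows, extra)
}
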