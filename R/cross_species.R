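#' GO-slim category profile of a top gene list
#'
#' Tallies up- and down-regulated genes per high-level (GO-slim style)
#' category. A gene contributes to every category it is annotated to, so
#' category totals may exceed the list size; genes with no annotation are
#' counted under `"unclassified"`.
#'
#' @param gene_list Gene-list tibble (`gene`, `direction`), typically a
#'   top-200 selection from [top_n_by_lfc()].
#' @param slim Tibble mapping `gene` to `category` (one row per pair).
#' @return A tibble with columns `category`, `n_up`, `n_down`.
#' @export
category_profile <- function(gene_list, slim) {
  if (nrow(gene_list) == 0) {
    return(tibble(category = character(), n_up = integer(), n_down = integer()))
  }
  ann <- inner_join(select(gene_list, "gene", "direction"), slim, by = "gene")
  unclassified <- filter(gene_list, !(.data$gene %in% slim$gene))
  if (nrow(unclassified) > 0) {
    ann <- bind_rows(ann, mutate(select(unclassified, "gene", "direction"),
                                 category = "unclassified"))
  }
  out <- summarise(group_by(ann, .data$category),
                   n_up = sum(.data$direction == "up"),
                   n_down = sum(.data$direction == "down"),
                   .groups = "drop")
  arrange(out, .data$category)
}

#' Shared functional gene families between two species' lists
#'
#' Table-driven formalization of a curated cross-species comparison: a
#' family is reported when it has at least one member in each species'
#' list. Direction-consistent matches are split into `up` (up-regulated in
#' both) and `down` rows; families whose members disagree in direction
#' between the species are reported in a separate `discordant` section. The
#' family map is an explicit input so curated groupings (solute carriers,
#' metallopeptidases, T-box factors, ...) are never inferred from symbols.
#'
#' @param list_a,list_b Gene-list tibbles (`gene`, `direction`) from the two
#'   species.
#' @param family_map Tibble mapping `gene` to `family`, covering symbols of
#'   both species.
#' @return A tibble: `family`, `direction` (`up`, `down`, `discordant`),
#'   `genes_a`, `genes_b` (comma-separated member symbols per species).
#' @export
#' @examples
#' a <- tibble::tibble(gene = c("SLC16A2", "SLC4A9"), direction = "up")
#' b <- tibble::tibble(gene = c("SLC13A1", "SLC35F1"), direction = "up")
#' fam <- tibble::tibble(gene = c(a$gene, b$gene), family = "solute carrier family")
#' shared_families(a, b, fam)
shared_families <- function(list_a, list_b, family_map) {
  fam_a <- inner_join(select(list_a, "gene", "direction"), family_map, by = "gene")
  fam_b <- inner_join(select(list_b, "gene", "direction"), family_map, by = "gene")
  fams <- intersect(unique(fam_a$family), unique(fam_b$family))
  rows <- purrr::map_dfr(sort(fams), function(f) {
    a <- filter(fam_a, .data$family == f)
    b <- filter(fam_b, .data$family == f)
    sections <- list()
    for (dir in c("up", "down")) {
      ga <- sort(unique(a$gene[a$direction == dir]))
      gb <- sort(unique(b$gene[b$direction == dir]))
      if (length(ga) > 0 && length(gb) > 0) {
        sections[[dir]] <- tibble(family = f, direction = dir,
                                  genes_a = paste(ga, collapse = ", "),
                                  genes_b = paste(gb, collapse = ", "))
      }
    }
    # mixed-direction pairs not already covered by a concordant row
    da <- sort(unique(a$gene))
    db <- sort(unique(b$gene))
    concordant <- length(sections) > 0
    dirs_a <- unique(a$direction)
    dirs_b <- unique(b$direction)
    if (!concordant && length(intersect(dirs_a, dirs_b)) == 0) {
      sections[["discordant"]] <- tibble(family = f, direction = "discordant",
                                         genes_a = paste(da, collapse = ", "),
                                         genes_b = paste(db, collapse = ", "))
    }
    bind_rows(sections)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(family = character(), direction = character(),
                   genes_a = character(), genes_b = character())
  }
  rows
}
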