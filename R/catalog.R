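#' The putrefaction pathway catalog
#'
#' A `putref_catalog` holds the pathway definitions the predictor works from:
#' for each pathway its substrate amino acid, product metabolite(s), and one
#' or more sub-pathways (alternative enzymatic routes to the same product).
#' Each sub-pathway lists enzyme components with EC numbers, Pfam-style
#' domain accessions, a proximity requirement, and an optional
#' `alternative_group` marking interchangeable enzymes for one reaction step.
#'
#' Sub-pathways carry a prediction category:
#' * **I** — all components must co-locate in one gene cluster;
#' * **II** — a core subset (`in_proximity`) must co-locate, remaining
#'   (distal) components need a homolog anywhere in the genome;
#' * **III** — a single reaction by a specific enzyme; presence of any one
#'   standalone component (or alternative-group member) suffices.
#'
#' Pathways flagged `evidence_only` (cresol, whose decarboxylase small
#' subunit has no characterized Pfam domain) are predicted from curated
#' external evidence lists instead of domain hits.
#'
#' @param pathways Tibble with one row per pathway: `pathway_id`, `name`,
#'   `substrate`, `products` (semicolon-delimited), `evidence_only`.
#' @param components Tibble with one row per enzyme component: `pathway_id`,
#'   `sub_id`, `category`, `component_id`, `ec_number`, `domain_ids`
#'   (semicolon-delimited), `role`, `alternative_group`, `in_proximity`,
#'   `evidence_only`.
#' @return A validated `putref_catalog` object.
#' @seealso [default_catalog()], [load_catalog()], [write_catalog()]
#' @export
new_catalog <- function(pathways, components) {
  cat <- structure(
    list(
      pathways = tibble::as_tibble(pathways),
      components = tibble::as_tibble(components)
    ),
    class = "putref_catalog"
  )
  validate_catalog(cat)
  cat
}

catalog_error <- function(msg) {
  abort(msg, class = "putrescan_catalog_error")
}

#' Validate a pathway catalog
#'
#' Checks structural invariants: unique ids, closed category and role
#' vocabularies, category I sub-pathways fully proximal, category III
#' sub-pathways standalone with empty proximity sets, non-empty domain sets
#' except for evidence-only components, and no dangling references.
#'
#' @param catalog A `putref_catalog`.
#' @return The catalog, invisibly, if valid; otherwise an error describing
#'   the offending pathway/component.
#' @export
validate_catalog <- function(catalog) {
  pw <- catalog$pathways
  cp <- catalog$components

  need_pw <- c("pathway_id", "name", "substrate", "products", "evidence_only")
  need_cp <- c("pathway_id", "sub_id", "category", "component_id", "ec_number",
               "domain_ids", "role", "alternative_group", "in_proximity",
               "evidence_only")
  miss <- setdiff(need_pw, names(pw))
  if (length(miss) > 0)
    catalog_error(paste0("catalog pathway table missing field(s): ",
                         paste(miss, collapse = ", ")))
  miss <- setdiff(need_cp, names(cp))
  if (length(miss) > 0)
    catalog_error(paste0("catalog component table missing field(s): ",
                         paste(miss, collapse = ", ")))

  if (anyDuplicated(pw$pathway_id))
    catalog_error(paste0("duplicate pathway_id: ",
                         paste(unique(pw$pathway_id[duplicated(pw$pathway_id)]),
                               collapse = ", ")))

  dangling <- setdiff(cp$pathway_id, pw$pathway_id)
  if (length(dangling) > 0)
    catalog_error(paste0("components reference undefined pathway(s): ",
                         paste(dangling, collapse = ", ")))
  empty <- setdiff(pw$pathway_id, cp$pathway_id)
  if (length(empty) > 0)
    catalog_error(paste0("pathway without components: ",
                         paste(empty, collapse = ", ")))

  dup <- cp |>
    dplyr::count(.data$pathway_id, .data$sub_id, .data$component_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    catalog_error(paste0("duplicate component_id within sub-pathway: ",
                         paste(dup$pathway_id, dup$component_id, sep = "/",
                               collapse = ", ")))

  bad_cat <- setdiff(unique(cp$category), c("I", "II", "III"))
  if (length(bad_cat) > 0)
    catalog_error(paste0("unknown category: ", paste(bad_cat, collapse = ", ")))
  bad_role <- setdiff(unique(cp$role), c("proximal-core", "distal", "standalone"))
  if (length(bad_role) > 0)
    catalog_error(paste0("unknown role: ", paste(bad_role, collapse = ", ")))

  mixed <- cp |>
    dplyr::distinct(.data$pathway_id, .data$sub_id, .data$category) |>
    dplyr::count(.data$pathway_id, .data$sub_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0)
    catalog_error(paste0("sub-pathway with conflicting categories: ",
                         paste(mixed$pathway_id, mixed$sub_id, sep = "/",
                               collapse = ", ")))

  off <- cp |> dplyr::filter(.data$role == "standalone", .data$category != "III")
  if (nrow(off) > 0)
    catalog_error(paste0("standalone role outside category III: ",
                         paste(off$pathway_id, off$component_id, sep = "/",
                               collapse = ", ")))
  off <- cp |> dplyr::filter(.data$category == "I", !.data$in_proximity)
  if (nrow(off) > 0)
    catalog_error(paste0("category I component outside proximity set: ",
                         paste(off$pathway_id, off$component_id, sep = "/",
                               collapse = ", ")))
  off <- cp |> dplyr::filter(.data$category == "III", .data$in_proximity)
  if (nrow(off) > 0)
    catalog_error(paste0("category III sub-pathway must have an empty proximity set: ",
                         paste(off$pathway_id, off$component_id, sep = "/",
                               collapse = ", ")))
  off <- cp |> dplyr::filter(.data$in_proximity, .data$role == "distal")
  if (nrow(off) > 0)
    catalog_error(paste0("distal component marked in_proximity: ",
                         paste(off$pathway_id, off$component_id, sep = "/",
                               collapse = ", ")))

  no_dom <- cp |>
    dplyr::filter(!.data$evidence_only,
                  is.na(.data$domain_ids) | !nzchar(.data$domain_ids))
  if (nrow(no_dom) > 0)
    catalog_error(paste0("component without domain accessions (and not evidence-only): ",
                         paste(no_dom$pathway_id, no_dom$component_id, sep = "/",
                               collapse = ", ")))

  invisible(catalog)
}

#' @export
print.putref_catalog <- function(x, ...) {
  cat("<putref_catalog> ", nrow(x$pathways), " pathways, ",
      nrow(x$components), " components, ",
      length(catalog_products(x)), " product metabolites\n", sep = "")
  print(catalog_overview(x), n = Inf)
  invisible(x)
}

#' Pathway-level overview of a catalog
#'
#' @param catalog A `putref_catalog`.
#' @return A tibble with one row per pathway: products, categories of its
#'   sub-pathways, sub-pathway and component counts.
#' @export
catalog_overview <- function(catalog) {
  subs <- catalog$components |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      categories = paste(sort(unique(.data$category)), collapse = "+"),
      n_sub = dplyr::n_distinct(.data$sub_id),
      n_components = dplyr::n(),
      .groups = "drop"
    )
  dplyr::left_join(catalog$pathways, subs, by = "pathway_id")
}

#' Distinct product metabolites of a catalog
#'
#' @param catalog A `putref_catalog`.
#' @return Character vector of distinct metabolite names.
#' @export
catalog_products <- function(catalog) {
  sort(unique(unlist(lapply(catalog$pathways$products, split_field))))
}

#' Domain accession index of a catalog
#'
#' Maps each domain accession to the pathway components it provides evidence
#' for. A domain may serve several components (shared domains across
#' pathways are allowed).
#'
#' @param catalog A `putref_catalog`.
#' @return A tibble with columns `domain_id`, `pathway_id`, `sub_id`,
#'   `component_id`.
#' @export
domain_index <- function(catalog) {
  catalog$components |>
    dplyr::mutate(domain_id = lapply(.data$domain_ids, split_field)) |>
    dplyr::select("domain_id", "pathway_id", "sub_id", "component_id") |>
    tidyr::unnest_longer("domain_id") |>
    dplyr::arrange(.data$domain_id, .data$pathway_id, .data$sub_id,
                   .data$component_id)
}

# Component "slots" of one sub-pathway: components sharing an
# alternative_group are interchangeable and form a single slot.
# Returns a tibble: slot_id, component_id, in_proximity, role.
sub_slots <- function(catalog, pathway, sub) {
  catalog$components |>
    dplyr::filter(.data$pathway_id == pathway, .data$sub_id == sub) |>
    dplyr::mutate(slot_id = dplyr::coalesce(.data$alternative_group,
                                            .data$component_id)) |>
    dplyr::select("slot_id", "component_id", "in_proximity", "role",
                  "evidence_only")
}

# placeholder Pfam-style accession for an EC number (see vignette: real
# accessions from domain curation should replace these via the config)
pdom <- function(ec) paste0("PDOM_", gsub("[.]", "_", ec))

#' The built-in putrefaction pathway catalog
#'
#' Ten pathways covering nine harmful putrefaction products: three
#' ammonia-releasing pathways (histidine degradation, THF production,
#' glutamate degradation), putrescine production from arginine via three
#' sub-pathways (ornithine decarboxylase, agmatinase, agmatine deiminase),
#' spermidine/spermine production, cresol (evidence-list based), and the
#' single-enzyme pathways for indole, phenol, cadaverine and H2S (the
#' latter with five interchangeable enzymes).
#'
#' Domain accessions are per-EC placeholders meant to be replaced by curated
#' Pfam accessions via [write_catalog()]/[load_catalog()]; the ornithine
#' decarboxylase route's `Arginase` and `OKR_DC_1` domains are the
#' literature-anchored exceptions used for fused-gene detection.
#'
#' @return A `putref_catalog` with 10 pathways.
#' @examples
#' cat <- default_catalog()
#' catalog_overview(cat)
#' catalog_products(cat)
#' @export
default_catalog <- function() {
  pathways <- tibble::tribble(
    ~pathway_id, ~name, ~substrate, ~products, ~evidence_only,
    "histidine_degradation", "Histidine degradation (histidine to glutamate)",
      "histidine", "ammonia", FALSE,
    "thf_production", "THF production (histidine to tetrahydrofolate)",
      "histidine", "ammonia", FALSE,
    "glutamate_degradation", "Glutamate degradation (glutamate to acetate + pyruvate)",
      "glutamate", "ammonia", FALSE,
    "putrescine_production", "Putrescine production (arginine to putrescine)",
      "arginine", "putrescine", FALSE,
    "spermidine_production", "Spermidine/spermine production (methionine route)",
      "methionine", "spermidine;spermine", FALSE,
    "cresol_production", "Cresol production (tyrosine via p-HPA, hpdBCA operon)",
      "tyrosine", "cresol", TRUE,
    "indole_production", "Indole production (tryptophanase)",
      "tryptophan", "indole", FALSE,
    "phenol_production", "Phenol production (tyrosine phenol-lyase)",
      "tyrosine", "phenol", FALSE,
    "cadaverine_production", "Cadaverine production (lysine decarboxylase)",
      "lysine", "cadaverine", FALSE,
    "h2s_production", "Hydrogen sulfide production (cysteine, five enzymes)",
      "cysteine", "H2S", FALSE
  )

  r <- function(pathway_id, sub_id, category, component_id, ec, domains,
                role, alt = NA_character_, prox = TRUE, ev = FALSE) {
    tibble::tibble(pathway_id = pathway_id, sub_id = sub_id,
                   category = category, component_id = component_id,
                   ec_number = ec, domain_ids = domains, role = role,
                   alternative_group = alt, in_proximity = prox,
                   evidence_only = ev)
  }

  components <- dplyr::bind_rows(
    # (a) ammonia: histidine -> glutamate, hut locus, category I
    r("histidine_degradation", "hut", "I", "hutH", "4.3.1.3", pdom("4.3.1.3"), "proximal-core"),
    r("histidine_degradation", "hut", "I", "hutU", "4.2.1.49", pdom("4.2.1.49"), "proximal-core"),
    r("histidine_degradation", "hut", "I", "hutI", "3.5.2.7", pdom("3.5.2.7"), "proximal-core"),
    # last step has two alternative enzymes: formiminoglutamase or
    # glutamate formyltransferase
    r("histidine_degradation", "hut", "I", "hutG", "3.5.3.8", pdom("3.5.3.8"),
      "proximal-core", alt = "formiminoglutamate_step"),
    r("histidine_degradation", "hut", "I", "ftcD", "2.1.2.5", pdom("2.1.2.5"),
      "proximal-core", alt = "formiminoglutamate_step"),

    # (a) ammonia: histidine -> THF, category I
    r("thf_production", "hut_thf", "I", "hutH", "4.3.1.3", pdom("4.3.1.3"), "proximal-core"),
    r("thf_production", "hut_thf", "I", "hutU", "4.2.1.49", pdom("4.2.1.49"), "proximal-core"),
    r("thf_production", "hut_thf", "I", "hutI", "3.5.2.7", pdom("3.5.2.7"), "proximal-core"),
    r("thf_production", "hut_thf", "I", "ftcD", "2.1.2.5", pdom("2.1.2.5"), "proximal-core"),
    r("thf_production", "hut_thf", "I", "ftcD_cyclodeaminase", "4.3.1.4",
      pdom("4.3.1.4"), "proximal-core"),

    # (a) ammonia: glutamate -> acetate + pyruvate, category II
    # (mutase + methylaspartate ammonia-lyase consecutive; other two distal)
    r("glutamate_degradation", "methylaspartate", "II", "glmE", "5.4.99.1",
      pdom("5.4.99.1"), "proximal-core"),
    r("glutamate_degradation", "methylaspartate", "II", "mal", "4.3.1.2",
      pdom("4.3.1.2"), "proximal-core"),
    r("glutamate_degradation", "methylaspartate", "II", "mesaconase", "4.2.1.34",
      pdom("4.2.1.34"), "distal", prox = FALSE),
    r("glutamate_degradation", "methylaspartate", "II", "citramalate_lyase", "4.1.3.22",
      pdom("4.1.3.22"), "distal", prox = FALSE),

    # (b) putrescine: ornithine decarboxylase route (category I; fused-gene
    # detection relies on the Arginase/OKR_DC_1 domain pair)
    r("putrescine_production", "odc", "I", "arginase", "3.5.3.1", "Arginase", "proximal-core"),
    r("putrescine_production", "odc", "I", "odc", "4.1.1.17", "OKR_DC_1", "proximal-core"),
    # (b) putrescine: agmatinase route, ADC operonic with agmatinase (cat I)
    r("putrescine_production", "agmatinase", "I", "adc", "4.1.1.19", pdom("4.1.1.19"),
      "proximal-core"),
    r("putrescine_production", "agmatinase", "I", "speB_agmatinase", "3.5.3.11",
      pdom("3.5.3.11"), "proximal-core"),
    # (b) putrescine: agmatine deiminase route, aguBA operon + distal ADC (cat II)
    r("putrescine_production", "agu", "II", "aguA", "3.5.3.12", pdom("3.5.3.12"),
      "proximal-core"),
    r("putrescine_production", "agu", "II", "aguB", "3.5.1.53", pdom("3.5.1.53"),
      "proximal-core"),
    r("putrescine_production", "agu", "II", "adc", "4.1.1.19", pdom("4.1.1.19"),
      "distal", prox = FALSE),

    # (c) spermidine/spermine: speD+speE operonic, metK distal (category II)
    r("spermidine_production", "spe", "II", "speD", "4.1.1.50", pdom("4.1.1.50"),
      "proximal-core"),
    r("spermidine_production", "spe", "II", "speE", "2.5.1.16", pdom("2.5.1.16"),
      "proximal-core"),
    r("spermidine_production", "spe", "II", "metK", "2.5.1.6", pdom("2.5.1.6"),
      "distal", prox = FALSE),

    # (d) cresol: hpdBCA operon; small subunit uncharacterized in Pfam, so
    # the whole pathway is predicted from curated evidence lists
    r("cresol_production", "hpd", "II", "hpdB", "4.1.1.83", pdom("4.1.1.83"),
      "proximal-core"),
    r("cresol_production", "hpd", "II", "hpdC", "", "", "proximal-core", ev = TRUE),
    r("cresol_production", "hpd", "II", "hpdA", "", pdom("hpdA"), "proximal-core"),

    # (e) single-reaction pathways, category III
    r("indole_production", "tna", "III", "tnaA", "4.1.99.1", pdom("4.1.99.1"),
      "standalone", prox = FALSE),
    r("phenol_production", "tpl", "III", "tpl", "4.1.99.2", pdom("4.1.99.2"),
      "standalone", prox = FALSE),
    r("cadaverine_production", "ldc", "III", "ldc", "4.1.1.18", pdom("4.1.1.18"),
      "standalone", prox = FALSE),
    # five interchangeable H2S-producing enzymes (curation slots)
    r("h2s_production", "cys", "III", "cystathionine_beta_synthase", "4.2.1.22",
      pdom("4.2.1.22"), "standalone", alt = "h2s_any", prox = FALSE),
    r("h2s_production", "cys", "III", "cystathionine_gamma_lyase", "4.4.1.1",
      pdom("4.4.1.1"), "standalone", alt = "h2s_any", prox = FALSE),
    r("h2s_production", "cys", "III", "mercaptopyruvate_sulfurtransferase", "2.8.1.2",
      pdom("2.8.1.2"), "standalone", alt = "h2s_any", prox = FALSE),
    r("h2s_production", "cys", "III", "cysteine_synthase", "2.5.1.47",
      pdom("2.5.1.47"), "standalone", alt = "h2s_any", prox = FALSE),
    r("h2s_production", "cys", "III", "cysteine_aminotransferase", "2.6.1.75",
      pdom("2.6.1.75"), "standalone", alt = "h2s_any", prox = FALSE)
  )

  new_catalog(pathways, components)
}

#' Load a pathway catalog from a YAML config file
#'
#' The config is a list of pathway entries; each pathway has `name`,
#' `substrate`, `products` (list), optional `evidence_only`, and
#' `sub_pathways`, each with `category`, a `components` list (fields
#' `component_id`, `ec_number`, `domain_ids`, `role`, optional
#' `alternative_group`, `evidence_only`), and a `proximity_set` list of
#' component ids. See the file shipped at
#' `system.file("extdata", "putrefaction_catalog.yml", package = "putrescan")`.
#'
#' @param path Path to a YAML catalog config.
#' @return A validated `putref_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path))
    catalog_error(paste0("catalog config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pathways))
    catalog_error("catalog config missing top-level 'pathways' list")

  pw_rows <- list()
  cp_rows <- list()
  for (p in cfg$pathways) {
    for (f in c("pathway_id", "name", "substrate", "products", "sub_pathways")) {
      if (is.null(p[[f]]))
        catalog_error(paste0("pathway '", p$pathway_id %||% "?",
                             "' missing required field '", f, "'"))
    }
    pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
      pathway_id = p$pathway_id, name = p$name, substrate = p$substrate,
      products = join_field(unlist(p$products)),
      evidence_only = isTRUE(p$evidence_only)
    )
    for (s in p$sub_pathways) {
      for (f in c("sub_id", "category", "components")) {
        if (is.null(s[[f]]))
          catalog_error(paste0("sub-pathway of '", p$pathway_id,
                               "' missing required field '", f, "'"))
      }
      comp_ids <- vapply(s$components, function(cc) cc$component_id %||% "",
                         character(1))
      prox <- unlist(s$proximity_set) %||% character(0)
      dangling <- setdiff(prox, comp_ids)
      if (length(dangling) > 0)
        catalog_error(paste0("sub-pathway '", p$pathway_id, "/", s$sub_id,
                             "' proximity_set references undefined component(s): ",
                             paste(dangling, collapse = ", ")))
      for (cc in s$components) {
        if (is.null(cc$component_id))
          catalog_error(paste0("component of '", p$pathway_id, "/", s$sub_id,
                               "' missing required field 'component_id'"))
        cp_rows[[length(cp_rows) + 1]] <- tibble::tibble(
          pathway_id = p$pathway_id, sub_id = s$sub_id,
          category = as.character(s$category),
          component_id = cc$component_id,
          ec_number = cc$ec_number %||% "",
          domain_ids = join_field(unlist(cc$domain_ids) %||% character(0)),
          role = cc$role %||% "proximal-core",
          alternative_group = cc$alternative_group %||% NA_character_,
          in_proximity = cc$component_id %in% prox,
          evidence_only = isTRUE(cc$evidence_only)
        )
      }
    }
  }
  new_catalog(dplyr::bind_rows(pw_rows), dplyr::bind_rows(cp_rows))
}

#' Write a pathway catalog to a YAML config file
#'
#' Serializes a catalog in the format read by [load_catalog()]; writing the
#' default catalog and re-loading it reproduces an identical object.
#'
#' @param catalog A `putref_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  pws <- lapply(seq_len(nrow(catalog$pathways)), function(i) {
    p <- catalog$pathways[i, ]
    comps <- catalog$components |> dplyr::filter(.data$pathway_id == p$pathway_id)
    subs <- lapply(unique(comps$sub_id), function(sid) {
      sc <- comps |> dplyr::filter(.data$sub_id == sid)
      list(
        sub_id = sid,
        category = sc$category[1],
        proximity_set = as.list(sc$component_id[sc$in_proximity]),
        components = lapply(seq_len(nrow(sc)), function(j) {
          cc <- sc[j, ]
          out <- list(component_id = cc$component_id,
                      ec_number = cc$ec_number,
                      domain_ids = as.list(split_field(cc$domain_ids)),
                      role = cc$role)
          if (!is.na(cc$alternative_group))
            out$alternative_group <- cc$alternative_group
          if (cc$evidence_only) out$evidence_only <- TRUE
          out
        })
      )
    })
    list(pathway_id = p$pathway_id, name = p$name, substrate = p$substrate,
         products = as.list(split_field(p$products)),
         evidence_only = p$evidence_only, sub_pathways = subs)
  })
  yaml::write_yaml(list(pathways = pws), path)
  invisible(path)
}

#' Export the catalog component table as TSV
#'
#' @param catalog A `putref_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_component_table <- function(catalog, path) {
  readr::write_tsv(catalog$components, path)
  invisible(path)
}
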