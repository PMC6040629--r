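# Declarative protein domain-architecture evidence. A rule is an ordered list
# of domain tokens (each accepting a set of Pfam names or name prefixes, with
# multiplicity one or one-or-more, optionally negated); a protein matches
# when the non-negated tokens occur as an ordered subsequence of its domain
# string (order optional per rule) and no negated token's name occurs
# anywhere. Transmembrane segments and signal peptides enter as the
# pseudo-domains "TM" and "SP". Rules carry an evidence level and a gene's
# classification is the strongest level whose rule matches.

#' Construct a domain token for an architecture rule
#'
#' @param names Exact domain names the token accepts.
#' @param prefix Name prefixes the token accepts (e.g. \code{"LRR"} accepts
#'   every Pfam LRR family variant).
#' @param min_count Required multiplicity: 1 = one, with \code{one_or_more}
#'   semantics covered since extra repeats never hurt.
#' @param negated If TRUE the token is forbidden: no accepted name may occur
#'   anywhere in the protein. Negated tokens carry no order constraint.
#' @return A \code{"rule_token"} object.
#' @export
rule_token <- function(names = character(0), prefix = character(0),
                       min_count = 1L, negated = FALSE) {
  stopifnot(length(names) + length(prefix) > 0L, min_count >= 1L)
  structure(list(names = names, prefix = prefix,
                 min_count = as.integer(min_count), negated = negated),
            class = "rule_token")
}

token_accepts <- function(token, domain_names) {
  hit <- domain_names %in% token$names
  for (p in token$prefix) hit <- hit | startsWith(domain_names, p)
  hit
}

#' Construct an architecture rule
#'
#' @param name Rule name (usually the gene it diagnoses).
#' @param level Evidence level: \code{"strong"}, \code{"moderate"} or
#'   \code{"weak"}.
#' @param tokens List of [rule_token()]s; at least one must be non-negated.
#' @param order_matters If TRUE non-negated tokens must appear in order.
#' @return An \code{"architecture_rule"} object.
#' @export
architecture_rule <- function(name, level, tokens, order_matters = TRUE) {
  level <- match.arg(level, c("strong", "moderate", "weak"))
  stopifnot(length(tokens) > 0L,
            all(vapply(tokens, inherits, TRUE, "rule_token")))
  if (all(vapply(tokens, function(t) t$negated, TRUE))) {
    stop("a rule needs at least one non-negated token", call. = FALSE)
  }
  structure(list(name = name, level = level, tokens = tokens,
                 order_matters = order_matters),
            class = "architecture_rule")
}

#' Resolve overlapping domain hits, best score first
#'
#' Greedy non-overlapping selection per protein in decreasing score order,
#' mirroring pfam_scan-like post-processing. Annotations without a
#' \code{score} column are returned sorted by start, untouched.
#'
#' @param ann Data.frame with columns \code{protein}, \code{domain},
#'   \code{start}, \code{end} and optionally \code{score}.
#' @return The filtered annotation, sorted by protein then start.
#' @export
resolve_overlaps <- function(ann) {
  stopifnot(all(c("protein", "domain", "start", "end") %in% names(ann)))
  if (!"score" %in% names(ann) || nrow(ann) == 0L) {
    return(ann[order(ann$protein, ann$start), , drop = FALSE])
  }
  keep <- logical(nrow(ann))
  for (idx in split(seq_len(nrow(ann)), ann$protein)) {
    taken <- idx[0]
    for (i in idx[order(-ann$score[idx])]) {
      clash <- any(ann$start[i] <= ann$end[taken] & ann$end[i] >= ann$start[taken])
      if (!clash) taken <- c(taken, i)
    }
    keep[taken] <- TRUE
  }
  out <- ann[keep, , drop = FALSE]
  out[order(out$protein, out$start), , drop = FALSE]
}

# ordered domain-name vector from a per-protein annotation (or pass through a
# character vector)
domain_string <- function(x) {
  if (is.character(x)) return(x)
  stopifnot(is.data.frame(x), all(c("domain", "start") %in% names(x)))
  x$domain[order(x$start)]
}

#' Match a protein's domain architecture against a rule
#'
#' @param annotation Character vector of domain names in positional order, or
#'   a one-protein annotation data.frame (columns \code{domain},
#'   \code{start}).
#' @param rule An [architecture_rule()].
#' @return Logical scalar.
#' @export
match_architecture <- function(annotation, rule) {
  domains <- domain_string(annotation)
  if (length(domains) == 0L) return(FALSE)
  for (token in rule$tokens) {
    if (token$negated && any(token_accepts(token, domains))) return(FALSE)
  }
  positive <- Filter(function(t) !t$negated, rule$tokens)
  if (rule$order_matters) {
    pos <- 0L
    for (token in positive) {
      idx <- which(token_accepts(token, domains))
      idx <- idx[idx > pos]
      if (length(idx) < token$min_count) return(FALSE)
      pos <- idx[token$min_count]
    }
    TRUE
  } else {
    all(vapply(positive, function(t) sum(token_accepts(t, domains)) >= t$min_count,
               TRUE))
  }
}

#' Classify the evidence level for one gene
#'
#' @param annotation As in [match_architecture()].
#' @param rules List of [architecture_rule()]s for one gene; evaluated
#'   strongest first.
#' @return \code{"strong"}, \code{"moderate"}, \code{"weak"} or \code{"none"}.
#' @export
classify_evidence <- function(annotation, rules) {
  order_lv <- c(strong = 1L, moderate = 2L, weak = 3L)
  rules <- rules[order(order_lv[vapply(rules, `[[`, "", "level")])]
  for (rule in rules) {
    if (match_architecture(annotation, rule)) return(rule$level)
  }
  "none"
}

#' The shipped domain-architecture rule library
#'
#' Diagnostic architectures for genes of interest in early animal evolution:
#' Toll-like receptors and their choanoflagellate kinase variants,
#' interleukin-receptor-like proteins, Notch and Delta, the Flamingo cadherin
#' at three evidence levels, Protocadherin, integrin beta, the RNAi machinery
#' (Argonaute, Dicer), TGF-beta pathway components (ligand, type-I receptor,
#' SMAD) and NLRs. LRR, TIR, Ank, EGF and kinase tokens accept the Pfam
#' family variants (e.g. any name beginning \code{"LRR"}, \code{TIR} or
#' \code{TIR_2}) since animal receptors mix members of these families freely.
#' Additional rules can be supplied alongside via [read_rule_library()].
#'
#' @return Named list: gene name to list of [architecture_rule()]s.
#' @export
default_rule_library <- function() {
  LRR <- function(...) rule_token(prefix = "LRR", ...)
  TIR <- function(...) rule_token(names = c("TIR", "TIR_2"), ...)
  TM <- function(...) rule_token(names = "TM", ...)
  kinase <- function(...) rule_token(prefix = "Pkinase", ...)
  EGF <- function(...) rule_token(prefix = "EGF", ...)
  one <- function(nm) rule_token(names = nm)
  list(
    TLR = list(
      architecture_rule("TLR", "strong", list(LRR(), TM(), TIR()))
    ),
    KinaseTLR = list(
      architecture_rule("KinaseTLR", "strong", list(LRR(), TM(), kinase(), TIR()))
    ),
    KinaseTIR = list(
      architecture_rule("KinaseTIR", "strong",
                        list(kinase(), TIR(), TM(negated = TRUE)),
                        order_matters = FALSE)
    ),
    InterleukinReceptor = list(
      architecture_rule("InterleukinReceptor", "strong",
                        list(rule_token(names = c("I-set", "V-set"), prefix = "Ig"),
                             TM(), TIR()))
    ),
    Notch = list(
      architecture_rule("Notch", "strong",
                        list(EGF(), one("Notch"), TM(),
                             rule_token(prefix = "Ank")))
    ),
    Delta = list(
      architecture_rule("Delta", "strong", list(one("MNNL"), one("DSL")),
                        order_matters = FALSE)
    ),
    Flamingo = list(
      architecture_rule("Flamingo", "strong",
                        list(one("Cadherin"), one("GPS"), one("7tm_2")),
                        order_matters = FALSE),
      architecture_rule("Flamingo", "moderate",
                        list(one("GPS"), one("7tm_2"),
                             rule_token(names = "HRM",
                                        prefix = c("EGF", "Laminin"))),
                        order_matters = FALSE),
      architecture_rule("Flamingo", "weak",
                        list(one("GPS"), one("7tm_2")), order_matters = FALSE)
    ),
    Protocadherin = list(
      architecture_rule("Protocadherin", "strong", list(one("Protocadherin")))
    ),
    IntegrinBeta = list(
      architecture_rule("IntegrinBeta", "strong", list(one("Integrin_beta")))
    ),
    Argonaute = list(
      architecture_rule("Argonaute", "strong",
                        list(one("DUF1785"), one("PAZ"), one("Piwi")))
    ),
    Dicer = list(
      architecture_rule("Dicer", "strong",
                        list(one("Dicer_dimer"), one("PAZ"),
                             one("Ribonuclease_3"))),
      architecture_rule("Dicer", "moderate", list(one("Dicer_dimer")))
    ),
    SMAD = list(
      architecture_rule("SMAD", "strong", list(one("MH1"), one("MH2")),
                        order_matters = FALSE)
    ),
    TGFBReceptor1 = list(
      architecture_rule("TGFBReceptor1", "strong",
                        list(one("TGF_beta_GS"), kinase()),
                        order_matters = FALSE)
    ),
    TGFBLigand = list(
      architecture_rule("TGFBLigand", "strong",
                        list(one("TGFb_propeptide"), one("TGF_beta")),
                        order_matters = FALSE)
    ),
    NLR = list(
      architecture_rule("NLR", "strong",
                        list(one("NACHT"), LRR(),
                             rule_token(names = c("Death", "CARD"))),
                        order_matters = FALSE)
    )
  )
}

#' Read an architecture rule library from YAML
#'
#' The YAML maps gene names to lists of rules; each rule has \code{level},
#' optional \code{order_matters} (default true) and \code{tokens}, each token
#' with \code{names} and/or \code{prefix}, optional \code{min_count} and
#' \code{negated}. Entries extend or override [default_rule_library()].
#'
#' @param path Path to the YAML file.
#' @param base Library to extend (default [default_rule_library()]).
#' @return Named list of rule lists.
#' @export
read_rule_library <- function(path, base = default_rule_library()) {
  spec <- yaml::read_yaml(path)
  for (gene in names(spec)) {
    base[[gene]] <- lapply(spec[[gene]], function(r) {
      tokens <- lapply(r$tokens, function(t) {
        rule_token(names = as.character(t$names %||% character(0)),
                   prefix = as.character(t$prefix %||% character(0)),
                   min_count = t$min_count %||% 1L,
                   negated = isTRUE(t$negated))
      })
      architecture_rule(gene, r$level, tokens,
                        order_matters = !isFALSE(r$order_matters))
    })
  }
  base
}

#' Evidence-level table across species
#'
#' Evaluates the rule library for every (species, gene) pair; a species'
#' evidence for a gene is the strongest classification among its proteins.
#'
#' @param annotations Data.frame with columns \code{species}, \code{protein},
#'   \code{domain}, \code{start}, \code{end} and optionally \code{score}
#'   (overlaps are resolved first when scores are present); TM/SP
#'   pseudo-domains included (see [read_phobius()]).
#' @param library Rule library (default [default_rule_library()]).
#' @param genes Genes to evaluate; unknown names are an error.
#' @return A character matrix (species x gene) of evidence levels.
#' @export
species_evidence_table <- function(annotations, library = default_rule_library(),
                                   genes = names(library)) {
  unknown <- setdiff(genes, names(library))
  if (length(unknown) > 0L) {
    stop("unknown gene(s) in rule library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ann <- resolve_overlaps(annotations)
  rank <- c(strong = 3L, moderate = 2L, weak = 1L, none = 0L)
  species <- sort(unique(ann$species))
  out <- matrix("none", nrow = length(species), ncol = length(genes),
                dimnames = list(species, genes))
  by_species <- split(ann, ann$species)
  for (sp in species) {
    proteins <- split(by_species[[sp]], by_species[[sp]]$protein)
    strings <- lapply(proteins, domain_string)
    for (g in genes) {
      levels <- vapply(strings, classify_evidence, "", rules = library[[g]])
      out[sp, g] <- names(rank)[match(max(rank[levels]), rank)]
    }
  }
  out
}

#' Read a pfam_scan-style domain annotation table
#'
#' Whitespace-delimited pfam_scan output (\code{#}-comment lines skipped):
#' sequence id, alignment start/end, envelope start/end, accession, name,
#' type, HMM coordinates, bit score, E-value, ... Only the protein, domain
#' name, alignment coordinates and bit score are retained. Protein ids may
#' carry the \code{"species|protein"} prefix, in which case a species column
#' is added.
#'
#' @param path Path to the pfam_scan output.
#' @return Annotation data.frame with columns \code{protein}, optionally
#'   \code{species}, \code{domain}, \code{start}, \code{end}, \code{score}.
#' @export
read_pfam_scan <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(), domain = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    stop(sprintf("malformed pfam_scan row at line %d", which(nf < 12L)[1L]),
         call. = FALSE)
  }
  out <- data.frame(
    protein = vapply(parts, `[[`, "", 1L),
    domain = vapply(parts, `[[`, "", 7L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    score = as.numeric(vapply(parts, `[[`, "", 12L)),
    stringsAsFactors = FALSE
  )
  if (all(grepl("|", out$protein, fixed = TRUE))) {
    out$species <- split_protein_ids(out$protein)$species
  }
  out
}

#' Read Phobius short-format output as TM/SP pseudo-domains
#'
#' Parses the PREDICTION column of Phobius short output: an optional signal
#' peptide \code{"n..c../cut"} prefix becomes an \code{"SP"} pseudo-domain
#' from residue 1 to the cut site, and every \code{start-end} transmembrane
#' segment becomes a \code{"TM"} pseudo-domain.
#'
#' @param path Path to the Phobius short output (header line optional).
#' @return Annotation data.frame with columns \code{protein}, \code{domain},
#'   \code{start}, \code{end}.
#' @export
read_phobius <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^SEQ", lines, ignore.case = TRUE)]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(f) < 4L) next
    id <- f[1L]; pred <- f[length(f)]
    if (startsWith(pred, "n")) {
      cut <- regmatches(pred, regexpr("/[0-9]+", pred))
      if (length(cut) == 1L) {
        cutpos <- as.integer(substring(cut, 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          protein = id, domain = "SP", start = 1L, end = cutpos - 1L,
          stringsAsFactors = FALSE)
        pred <- sub("^.*?/[0-9]+", "", pred)
      }
    }
    tm <- regmatches(pred, gregexpr("[0-9]+-[0-9]+", pred))[[1L]]
    for (seg in tm) {
      se <- as.integer(strsplit(seg, "-", fixed = TRUE)[[1L]])
      rows[[length(rows) + 1L]] <- data.frame(
        protein = id, domain = "TM", start = se[1L], end = se[2L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein = character(), domain = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$protein, out$start), , drop = FALSE]
}
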