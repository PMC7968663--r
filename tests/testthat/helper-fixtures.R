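# Fixture builders shared across test files.

# Minimal DrugBank-dialect XML with configurable drugs. Each drug spec:
# list(id, name, groups = c(...), targets = list(c(id, name, organism)),
# enzymes = ..., carriers = ..., transporters = ...).
drugbank_xml_fixture <- function(drugs) {
  partner_block <- function(tag_plural, tag, partners) {
    if (is.null(partners) || length(partners) == 0) return("")
    inner <- vapply(partners, function(p) {
      org <- if (length(p) >= 3) sprintf("<organism>%s</organism>", p[3]) else ""
      sprintf("<%s><id>%s</id><name>%s</name>%s</%s>",
              tag, p[1], if (length(p) >= 2) p[2] else p[1], org, tag)
    }, character(1))
    sprintf("<%s>%s</%s>", tag_plural, paste(inner, collapse = ""), tag_plural)
  }
  drug_block <- vapply(drugs, function(d) {
    groups <- paste(sprintf("<group>%s</group>", d$groups %||% character(0)),
                    collapse = "")
    sprintf(
      paste0("<drug><drugbank-id primary=\"true\">%s</drugbank-id>",
             "<name>%s</name><groups>%s</groups>%s%s%s%s</drug>"),
      d$id, d$name %||% d$id, groups,
      partner_block("targets", "target", d$targets),
      partner_block("enzymes", "enzyme", d$enzymes),
      partner_block("carriers", "carrier", d$carriers),
      partner_block("transporters", "transporter", d$transporters)
    )
  }, character(1))
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?><drugbank>",
         paste(drug_block, collapse = ""), "</drugbank>")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Four-drug / four-target fixture used by several modules:
# shared targets induce the coregulation pairs D1-D2 (T1) and D2-D3 (T2).
chain_fixture <- function() {
  interaction_table(tibble::tibble(
    drug_id = c("D1", "D2", "D2", "D3"),
    target_id = c("T1", "T1", "T2", "T2")
  ))
}
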