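# Column dialects for rearrangement tables. Adding a vendor dialect is
# config-only: map the five logical fields and give the on-disk column order.
immunoseq:
  columns:
    cdr3_nt: "nucleotide"
    cdr3_aa: "aminoAcid"
    v_gene: "vGeneName"
    j_gene: "jGeneName"
    templates: "count (templates)"
    productive: "sequenceStatus"
  # sequenceStatus is "In" (in-frame, productive), "Out" or "Stop"
  productive_true: "In"
  productive_false: ["Out", "Stop"]
  order:
    - "nucleotide"
    - "aminoAcid"
    - "count (templates)"
    - "vGeneName"
    - "jGeneName"
    - "sequenceStatus"
airr:
  columns:
    cdr3_nt: "junction"
    cdr3_aa: "junction_aa"
    v_gene: "v_call"
    j_gene: "j_call"
    templates: "duplicate_count"
    productive: "productive"
  productive_true: ["T", "TRUE", "true"]
  productive_false: ["F", "FALSE", "false"]
  order:
    - "junction"
    - "junction_aa"
    - "duplicate_count"
    - "v_call"
    - "j_call"
    - "productive"
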