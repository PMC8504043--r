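{
  "comment": "Administration-route vocabulary. 'risky' lists invasive or error-prone routes; any token with a prefix in 'risky_prefixes' is risky as well. Tokens are matched after lowercasing and stripping hyphens/spaces.",
  "vocabulary": [
    "peroral", "transdermal", "ocular", "nasal", "rectal", "vaginal",
    "inhalative", "topical", "buccal", "sublingual", "auricular", "dental",
    "endotracheal", "endo-cervical", "epidural", "epilesional",
    "extra-amniotic", "gastrointestinal", "gingival", "laryngopharyngeal",
    "ossal", "para-cervical", "periarticular", "peribulbar", "perineural",
    "periosteal", "retrobulbar", "sub-tenon", "subconjunctival",
    "subcutaneous", "sublesional", "submucosal", "urethral", "via-probe",
    "intravenous", "intramuscular", "intraarterial", "intrathecal",
    "intraarticular", "intravesical", "intracardiac", "intradermal",
    "intraocular", "intraosseous", "intraperitoneal", "intravitreal",
    "intralesional", "intrauterine"
  ],
  "risky": [
    "endotracheal", "endo-cervical", "epidural", "epilesional",
    "extra-amniotic", "gastrointestinal", "gingival", "laryngopharyngeal",
    "ossal", "para-cervical", "periarticular", "peribulbar", "perineural",
    "periosteal", "retrobulbar", "sub-tenon", "subconjunctival",
    "subcutaneous", "sublesional", "submucosal", "urethral", "via-probe"
  ],
  "risky_prefixes": ["intra"]
}
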