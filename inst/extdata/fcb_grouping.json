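{
  "name": "FCB",
  "target_group": ["Fritillaria cirrhosa", "Fritillaria unibracteata", "Fritillaria przewalskii", "Fritillaria delavayi", "Fritillaria taipaiensis", "Fritillaria wabuensis"],
  "adulterants": ["Fritillaria hupehensis", "Fritillaria ussuriensis", "Fritillaria thunbergii", "Fritillaria pallidiflora", "Fritillaria walujewii"],
  "joint_taxa": {
    "FPB": ["Fritillaria pallidiflora", "Fritillaria walujewii"]
  }
}
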