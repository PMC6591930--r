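# Registry of the 15 annotation servers of the first continuous evaluation
# campaign. Names, contacts, institutions, output formats, languages,
# licenses and references are transcribed from the published overview table.
# Two elements are synthetic stand-ins (hence the filename): the software
# `version` (mandatory tier, not printed in the table; set to "1.0"
# throughout) and the per-server entity-type assignments, which were
# reconstructed to match the published marginals exactly (servers per type
# and types per server) because the per-cell support marks are not
# machine-recoverable from the source table.
servers:
- server_id: 103
  name: SIA
  admin_contact: Philippe Thomas
  institution: German Research Center for Artificial Intelligence
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [organism, gene, tissue_organ]
  license: Apache License 2
  references: [CR37, CR38]
  location: Germany
- server_id: 106
  name: LeadMine WS
  admin_contact: Daniel Lowe
  institution: NextMove Software
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [chemical, protein, disease, organism, cell_line_type,
                    gene, subcellular_structure, tissue_organ]
  location: Ireland
- server_id: 107
  name: SCHEMA
  admin_contact: Hong-Jie Dai
  institution: National Taitung University
  programming_language: "C#"
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [chemical]
  references: [CR39]
  location: Republic of China (Taiwan)
- server_id: 108
  name: MRI
  admin_contact: Chen-Kai Wang
  institution: Taipei Medical University
  programming_language: "C#"
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [mutation]
  references: [CR40]
  location: Republic of China (Taiwan)
- server_id: 111
  name: DiseaseExtract
  admin_contact: Jitendra Jonnagaddala
  institution: UNSW Australia
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [disease]
  license: Apache License 2
  references: [CR41]
  location: Australia
- server_id: 114
  name: Tagger
  admin_contact: Lars Juhl Jensen
  institution: University of Copenhagen
  programming_language: C++
  version: "1.0"
  supported_formats: [bioc_json, tsv]
  supported_types: [chemical, protein, disease, organism, gene, tissue_organ]
  license: The BSD 2-Clause 'Simplified' or 'FreeBSD' License
  references: [CR42, CR43]
  location: Denmark
- server_id: 116
  name: Neji - BeCalm TIPS Task
  admin_contact: "André Santos"
  institution: IEETA - Institute of Electronics and Informatics Engineering of Aveiro
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_xml, bioc_json, tsv]
  supported_types: [chemical, protein, disease, organism, cell_line_type,
                    gene, subcellular_structure, tissue_organ, mirna]
  license: CC by-nc-sa 3.0
  references: [CR44, CR45]
  location: Portugal
- server_id: 117
  name: MER
  admin_contact: "André Lamúrias"
  institution: "LaSIGE, Faculdade de Ciências, Universidade de Lisboa, Portugal"
  programming_language: Bash
  version: "1.0"
  supported_formats: [tsv]
  supported_types: [chemical, protein, disease, organism,
                    anatomical_component, cell_line_type, gene]
  license: MIT
  references: [CR46, CR47]
  location: Portugal
- server_id: 120
  name: Olelo
  admin_contact: Hendrik Folkerts
  institution: Hasso Plattner Institute
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_xml]
  supported_types: [chemical, protein, disease, organism,
                    anatomical_component, cell_line_type, gene,
                    subcellular_structure, mirna, go]
  references: [CR48]
  location: Germany
- server_id: 121
  name: LeadMine WS (AWS Free Tier)
  admin_contact: Daniel Lowe
  institution: NextMove Software
  programming_language: Java
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [chemical, protein, disease, anatomical_component,
                    gene, mirna]
  location: United States of America
- server_id: 122
  name: OntoGene
  admin_contact: Lenz Furrer
  institution: "Institute for Computational Linguistics, University of Zurich"
  programming_language: Python
  version: "1.0"
  supported_formats: [bioc_xml, bioc_json, tsv]
  supported_types: [chemical, anatomical_component, cell_line_type,
                    subcellular_structure, mirna]
  license: GNU Affero General Public License
  references: [CR49, CR50]
  location: Switzerland
- server_id: 124
  name: TextImager CempS
  admin_contact: Wahed Hemati
  institution: "Text Technology Lab - Goethe-Universität Frankfurt"
  programming_language: Java
  version: "1.0"
  supported_formats: [tsv]
  supported_types: [chemical, cell_line_type, mutation,
                    subcellular_structure, mirna]
  references: [CR51]
  location: Germany
- server_id: 126
  name: TextImager GproM
  admin_contact: Wahed Hemati
  institution: "Text Technology Lab - Goethe-Universität Frankfurt"
  programming_language: Java
  version: "1.0"
  supported_formats: [tsv]
  supported_types: [chemical, protein, disease, cell_line_type, mutation,
                    subcellular_structure, mirna]
  references: [CR51]
  location: Germany
- server_id: 127
  name: READ-Biomed
  admin_contact: Read Biomed
  institution: University of Melbourne
  programming_language: Java/Scala
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [disease]
  references: [CR52]
  location: Australia
- server_id: 128
  name: NLProt
  admin_contact: Miguel Madrid
  institution: Structural Computational Biology Group of the CNIO
  programming_language: Crystal
  version: "1.0"
  supported_formats: [bioc_json]
  supported_types: [mutation, subcellular_structure, tissue_organ]
  license: MIT
  references: [CR53]
  location: Spain
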