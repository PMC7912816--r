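{
  "name": "truffle-harvest-record",
  "format": "csv",
  "dialect": {
    "delimiter": ",",
    "encoding": "UTF-8",
    "header": true,
    "decimal": ".",
    "date_format": "ISO-8601"
  },
  "fields": [
    {"name": "season", "type": "string", "required": true,
     "description": "Fruiting-season label, e.g. 2016-2017 (November of the first year to March of the second)"},
    {"name": "block", "type": "string", "required": true,
     "description": "Replicate block label"},
    {"name": "typology", "type": "string", "required": true,
     "enum": ["substrate", "BS1", "BS2", "BS3"],
     "description": "Soil typology: peat-based substrate or bulk soil of blocks 1-3"},
    {"name": "dig_id", "type": "string", "required": true,
     "description": "Identifier of the excavation spot; shared by all fruitbodies of a cluster"},
    {"name": "dig_type", "type": "string", "required": true,
     "enum": ["single", "cluster"],
     "description": "Whether the dig held one fruitbody or several"},
    {"name": "harvest_date", "type": "date", "required": true,
     "description": "Calendar date of the survey the dig was excavated on"},
    {"name": "depth_class", "type": "integer", "required": true, "minimum": 1,
     "description": "10-cm fruiting-depth interval index of the dig (1 = 0-10 cm)"},
    {"name": "weight_g", "type": "number", "required": true,
     "exclusiveMinimum": 0, "description": "Fresh weight in grams"},
    {"name": "dmax_mm", "type": "number", "required": false,
     "exclusiveMinimum": 0, "description": "Maximum caliper diameter, mm"},
    {"name": "dmin_mm", "type": "number", "required": false,
     "exclusiveMinimum": 0,
     "description": "Minimum caliper diameter, mm (<= dmax_mm)"},
    {"name": "shape_index", "type": "integer", "required": true,
     "minimum": 1, "maximum": 9,
     "description": "Nine-category shape score; higher = rounder, more regular"},
    {"name": "maturity", "type": "number", "required": false,
     "minimum": 0, "maximum": 1,
     "description": "Spore maturity index: proportion of >= 50 sampled asci with mature spores; recorded for single fruitbodies"},
    {"name": "role", "type": "string", "required": true,
     "enum": ["single", "largest", "other"],
     "description": "Within-dig role; a cluster has exactly one 'largest' record carrying the maximal weight"}
  ],
  "dig_invariants": [
    "a dig with dig_type=single has exactly one record",
    "a cluster dig has >= 2 records, exactly one with role=largest, which has the maximal weight in the dig"
  ]
}
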