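{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dockzones frequency matrix export",
  "type": "object",
  "required": ["n", "d_min", "d_max", "rows", "cols", "cells"],
  "properties": {
    "n": {"type": "integer", "minimum": 1},
    "d_min": {"type": "number", "exclusiveMinimum": 0},
    "d_max": {"type": "number"},
    "rows": {"type": "array", "items": {"$ref": "#/definitions/residue"}},
    "cols": {"type": "array", "items": {"$ref": "#/definitions/residue"}},
    "cells": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["row_key", "col_key", "count"],
        "properties": {
          "row_key": {"type": "string"},
          "col_key": {"type": "string"},
          "count": {"type": "integer", "minimum": 1}
        }
      }
    }
  },
  "definitions": {
    "residue": {
      "type": "object",
      "required": ["key", "chain", "number", "name"],
      "properties": {
        "key": {"type": "string"},
        "chain": {"type": "string"},
        "number": {"type": "integer"},
        "inscode": {"type": "string"},
        "name": {"type": "string"}
      }
    }
  }
}
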