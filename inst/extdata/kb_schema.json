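{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "vrikshadx knowledge base",
  "description": "Declarative knowledge base for the plant-disorder diagnostic shell: disorder descriptions, yes/no symptom questions, and treatments, with explicit id cross-references. Arrays are semantically ordered (disorder order drives hypothesis order). Referential integrity and rule distinguishability are enforced by validate_kb(), beyond what JSON Schema expresses.",
  "type": "object",
  "required": ["schema_version", "symptoms", "disorders"],
  "properties": {
    "schema_version": {"type": "string"},
    "symptoms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "question_text"],
        "properties": {
          "id": {"type": "string", "pattern": "^[a-z][a-z0-9_]*$"},
          "question_text": {"type": "string", "pattern": "\\?$"},
          "label": {"type": "string"}
        }
      }
    },
    "disorders": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "category", "subcategory", "symptom_ids"],
        "properties": {
          "id": {"type": "string", "pattern": "^[a-z][a-z0-9_]*$"},
          "name": {"type": "string"},
          "category": {"enum": ["internal", "external"]},
          "subcategory": {
            "enum": ["vata", "pitta", "kapha", "insects", "cold", "wind", "sun", "general"]
          },
          "description": {"type": "string"},
          "curated": {"type": "boolean", "default": false},
          "symptom_ids": {
            "type": "array", "items": {"type": "string"}, "minItems": 1,
            "uniqueItems": true
          },
          "treatment_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "treatments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "description"],
        "properties": {
          "id": {"type": "string", "pattern": "^[a-z][a-z0-9_]*$"},
          "description": {"type": "string"},
          "ingredients": {"type": "array", "items": {"type": "string"}},
          "source_note": {"type": "string"}
        }
      }
    }
  }
}
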