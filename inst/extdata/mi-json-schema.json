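{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "rpsimi:mi-json-schema:1.0",
  "title": "MI-JSON (rpsimi dialect, version 1.0)",
  "description": "Write-only JSON dialect of molecular interaction data for JavaScript viewer clients. The 'data' array holds each distinct interactor exactly once, sorted by preferred identifier, followed by interaction objects in input order. Participant references (interactorA/interactorB id) must resolve to an interactor object in the same document.",
  "type": "object",
  "required": ["format", "version", "data"],
  "properties": {
    "format": { "const": "mi-json" },
    "version": { "type": "string" },
    "data": {
      "type": "array",
      "items": {
        "oneOf": [
          {
            "type": "object",
            "required": ["object", "id", "label", "type"],
            "properties": {
              "object": { "const": "interactor" },
              "id": { "type": "string", "minLength": 1 },
              "label": { "type": "string" },
              "type": { "type": "string" },
              "organism": {
                "type": "object",
                "required": ["taxid"],
                "properties": {
                  "taxid": { "type": "integer" },
                  "name": { "type": "string" }
                }
              },
              "sequence": { "type": "string" }
            }
          },
          {
            "type": "object",
            "required": ["object", "id", "interactorA", "interactorB"],
            "properties": {
              "object": { "const": "interaction" },
              "id": { "type": "string", "minLength": 1 },
              "interactorA": { "$ref": "#/definitions/participant" },
              "interactorB": { "$ref": "#/definitions/participant" },
              "interactionType": { "type": "string" },
              "detectionMethod": { "type": "string" },
              "sourceIds": { "type": "array", "items": { "type": "string" } },
              "confidences": { "type": "array", "items": { "type": "string" } },
              "expansion": { "type": "string" },
              "negative": { "type": "boolean" }
            }
          }
        ]
      }
    }
  },
  "definitions": {
    "participant": {
      "type": "object",
      "required": ["id"],
      "properties": {
        "id": { "type": "string", "minLength": 1 },
        "biologicalRole": { "type": "string" },
        "experimentalRole": { "type": "string" },
        "stoichiometry": { "type": "integer" },
        "features": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["type", "ranges"],
            "properties": {
              "type": { "type": "string" },
              "ranges": {
                "type": "array",
                "items": { "type": "string", "pattern": "^([0-9]+|\\?)-([0-9]+|\\?)$" }
              }
            }
          }
        }
      }
    }
  }
}
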