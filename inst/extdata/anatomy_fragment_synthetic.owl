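<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic hand-written fragment in the style of the NCI human anatomy
     ontology, for reader tests. Not an excerpt of the real ontology. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="http://example.org/nci#NCI_C33854">
    <rdfs:label>Vascular_System</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://example.org/nci#NCI_C25762"/>
    <rdfs:subClassOf>
      <owl:Restriction>
        <owl:onProperty rdf:resource="http://example.org/nci#part_of"/>
        <owl:someValuesFrom rdf:resource="http://example.org/nci#NCI_C12686"/>
      </owl:Restriction>
    </rdfs:subClassOf>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/nci#NCI_C25762">
    <rdfs:label>Organ_System</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/nci#NCI_C12686">
    <rdfs:label>Cardiovascular_System</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/nci#NCI_C33894">
    <rdfs:label>Vascular_Endothelium</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/nci#NCI_C21599">
    <rdfs:label>Plant_Part</rdfs:label>
    <owl:disjointWith rdf:resource="http://example.org/nci#NCI_C25444"/>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/nci#NCI_C25444">
    <rdfs:label>Animal_Part</rdfs:label>
  </owl:Class>
  <owl:AllDisjointClasses>
    <owl:members rdf:parseType="Collection">
      <owl:Class rdf:about="http://example.org/nci#NCI_C33854"/>
      <owl:Class rdf:about="http://example.org/nci#NCI_C33894"/>
      <owl:Class rdf:about="http://example.org/nci#NCI_C12686"/>
    </owl:members>
  </owl:AllDisjointClasses>
</rdf:RDF>
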